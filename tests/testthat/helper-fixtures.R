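# shared fixtures, built in code

quartet_library <- function() make_reference_library()

# absorbance spectrum from known coefficients on the library grid
mixture_spectrum <- function(lib, coefs) {
  chrom <- colnames(lib$refs)
  vals <- drop(lib$refs %*% as.numeric(coefs[chrom])) +
    lib$grid * coefs[["slope"]] + coefs[["intercept"]]
  spectrum(lib$grid, vals, role = "absorbance", name = "synthetic mixture")
}

# closed-form normal-equations solution over the model band (oracle)
normal_equations_fit <- function(absorbance, model) {
  lib <- align_library(model$library, absorbance$wavelengths_nm)
  idx <- which(lib$grid >= model$band_nm[1] & lib$grid <= model$band_nm[2])
  X <- cbind(lib$refs[idx, , drop = FALSE], slope = lib$grid[idx],
             intercept = 1)
  y <- absorbance$values[idx]
  drop(solve(crossprod(X), crossprod(X, y)))
}

default_coefs <- function(fbl = 0.58, b_total = 0.05) {
  data.frame(b_H = (1 - fbl) * b_total, b_L = fbl * b_total,
             c1 = 0.03, c = 0.04, slope = 2e-4, intercept = 0.05)
}

heart_coefs <- function(fbl = 0.58, b_total = 0.2) {
  data.frame(b_H = (1 - fbl) * b_total, b_L = fbl * b_total,
             c1 = 0.12, c = 0.16, slope = 0, intercept = 0.1)
}
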