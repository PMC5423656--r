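.onLoad <- function(libname, pkgname) {
  .load_param_sets()
  # coupled-cell sets live in the same directory
  dir <- system.file("extdata", package = pkgname)
  for (nm in c("me_vl", "me_dm")) {
    f <- file.path(dir, paste0("params_", nm, ".txt"))
    if (file.exists(f))
      assign(nm, read_clock_params(f, base = "zero"), envir = .param_sets)
  }
  invisible()
}
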