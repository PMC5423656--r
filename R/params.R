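#' @useDynLib meclock
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

# Canonical parameter and state orderings. Every routine in the package
# addresses parameters by these symbols; the vector layout is also the layout
# handed to the compiled right-hand side, so order changes are breaking.
.param_names <- c(
  paste0("vs", 1:5),
  paste0("v", 1:11),
  paste0("ke", 1:11),
  paste0("kd", 1:13),
  paste0("k", 1:7),
  paste0("kp", 1:4),
  paste0("ka", 1:4),
  "kI1", "kx", "kk",
  "m", "w", "s"
)

.state_names <- c("Mp1", "Mp2", "P1c", "P1n", "P2c", "P2n",
                  "MB", "Bc", "BN", "MR", "R", "PB1", "PB2")

.hill_names <- c("m", "w", "s")

#' Parameter and state vocabulary of the clock model
#'
#' `clock_param_names()` returns the 61 parameter symbols of the single-cell
#' model in their canonical order: transcription rates `vs1..vs5`, maximal
#' enzymatic degradation rates `v1..v11`, Michaelis constants `ke1..ke11`,
#' first-order degradation constants `kd1..kd13`, synthesis/transport rates
#' `k1..k7`, complex association/dissociation constants `kp1..kp4`,
#' activation constants `ka1..ka4`, the REV-ERBa inhibition constant `kI1`,
#' auxiliary constants `kx` and `kk`, and Hill coefficients `m`, `w`, `s`.
#' `clock_state_names()` returns the 13 state-variable names: per1/per2 mRNA
#' (`Mp1`, `Mp2`), cytosolic and nuclear PER1/PER2 (`P1c`, `P1n`, `P2c`,
#' `P2n`), Bmal1 mRNA and BMAL1 protein (`MB`, `Bc`, `BN`), Rev-erba mRNA and
#' protein (`MR`, `R`) and the PER-BMAL1 complexes (`PB1`, `PB2`).
#'
#' @return A character vector of symbols.
#' @export
clock_param_names <- function() .param_names

#' @rdname clock_param_names
#' @export
clock_state_names <- function() .state_names

#' Construct a full clock parameter vector
#'
#' Builds a named numeric vector holding all 61 kinetic constants of the
#' single-cell model, starting from one of the calibrated base sets shipped
#' with the package and applying any overrides given as name = value pairs.
#'
#' The shipped sets were calibrated by the package authors (genetic algorithm
#' followed by Levenberg-Marquardt refinement) against hallmark quantities of
#' the mammalian SCN clock: a free-running period of 23.75 h in constant
#' darkness, the canonical peak-phase ordering of the clock transcripts and
#' proteins, the shortened free-running periods of the per1 and per2 single
#' mutants, and entrained peak phases under light-dark cycles. They are this
#' package's own calibration, not a published table.
#'
#' @param ... Named overrides, e.g. `vs1 = 0`. Unknown symbols are an error.
#' @param set Base set: `"wt_dd"` (default; used for DD and LD work),
#'   `"wt_ll"` (recalibrated for constant-light period/intensity curves), or
#'   `"zero"` (all rates 0, Hill coefficients 1; useful for building test
#'   systems from scratch).
#' @return Named numeric vector of length 61 with class `clock_params`.
#' @examples
#' p <- clock_params()
#' p_mut <- clock_params(vs1 = 0)
#' @export
clock_params <- function(..., set = c("wt_dd", "wt_ll", "zero")) {
  set <- match.arg(set)
  base <- switch(set,
    wt_dd = .param_sets$wt_dd,
    wt_ll = .param_sets$wt_ll,
    zero  = setNames(c(rep(0, 58), 1, 1, 1), .param_names)
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("all parameter overrides must be named", call. = FALSE)
    bad <- setdiff(names(overrides), .param_names)
    if (length(bad))
      stop("unknown parameter symbol(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    base[names(overrides)] <- unlist(overrides)
  }
  validate_clock_params(base)
}

validate_clock_params <- function(p) {
  p <- p[.param_names]  # enforce canonical order
  if (anyNA(p) || any(!is.finite(p)))
    stop("clock parameters must be finite and complete", call. = FALSE)
  if (any(p < 0))
    stop("rate and affinity constants must be >= 0: ",
         paste(names(p)[p < 0], collapse = ", "), call. = FALSE)
  if (any(p[.hill_names] < 1))
    stop("Hill coefficients m, w, s must be >= 1", call. = FALSE)
  structure(p, class = c("clock_params", "numeric"))
}

#' @export
print.clock_params <- function(x, ...) {
  cat("<clock_params> 61 kinetic constants\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Construct a clock state vector
#'
#' @param ... Named components (see [clock_state_names()]); unnamed defaults
#'   fill the remaining components.
#' @param default Value used for components not given explicitly (0.1 nM;
#'   the limit cycle is reached from any positive start after the transient).
#' @return Named numeric vector of length 13.
#' @export
clock_state <- function(..., default = 0.1) {
  s <- setNames(rep(default, 13), .state_names)
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), .state_names)
    if (length(bad))
      stop("unknown state component(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    s[names(overrides)] <- unlist(overrides)
  }
  if (anyNA(s) || any(!is.finite(s)))
    stop("state components must be finite", call. = FALSE)
  if (any(s < 0))
    stop("state components must be >= 0: ",
         paste(names(s)[s < 0], collapse = ", "), call. = FALSE)
  s
}

# ---------------------------------------------------------------------------
# Mutant genotypes

.mutant_overrides <- list(
  wild_type   = list(),
  # per1 knockout refit: per2 limb carries the rhythm
  per1        = list(vs1 = 0, v4 = 0.43, kp4 = 0.19),
  # rhythmic per2 allele: knockout plus co-adjusted per1-limb kinetics
  per2_ldc    = list(vs1 = 0.7, vs2 = 0, vs3 = 4.5, vs5 = 0.5,
                     v1 = 0.44, v2 = 1.38, v3 = 1.67,
                     k1 = 1.44, kd3 = 0.08, kp1 = 0.11, kp2 = 0.18),
  # arrhythmic per2 allele: plain transcriptional knockout
  per2_Brdm1  = list(vs2 = 0),
  per1_per2   = list(vs1 = 0, vs2 = 0),
  bmal1       = list(vs3 = 0, vs4 = 0),
  rev_erba    = list(vs5 = 0)
)

#' Genotype presets and mutant parameter overrides
#'
#' `clock_genotypes()` lists the built-in genotype labels. `mutant_overrides()`
#' returns the parameter replacements a genotype applies on top of the
#' wild-type set: each knockout zeroes the relevant transcription rate(s), and
#' the rhythmic alleles (`per1`, `per2_ldc`) additionally carry the
#' co-adjusted accessory kinetics of that genotype's refit. `apply_mutant()`
#' returns a copy of `params` with only those symbols replaced.
#'
#' @param genotype One of `"wild_type"`, `"per1"`, `"per2_ldc"`,
#'   `"per2_Brdm1"`, `"per1_per2"`, `"bmal1"`, `"rev_erba"`.
#' @param params A `clock_params` vector.
#' @param overrides Optional explicit named list of symbol = value overrides
#'   used instead of a genotype preset.
#' @return `apply_mutant()`: a `clock_params` vector.
#' @examples
#' p <- apply_mutant(clock_params(), "per1")
#' p[["vs1"]]  # 0
#' @export
clock_genotypes <- function() names(.mutant_overrides)

#' @rdname clock_genotypes
#' @export
mutant_overrides <- function(genotype) {
  if (!genotype %in% names(.mutant_overrides))
    stop("unknown genotype label: ", genotype, call. = FALSE)
  .mutant_overrides[[genotype]]
}

#' @rdname clock_genotypes
#' @export
apply_mutant <- function(params, genotype = "wild_type", overrides = NULL) {
  params <- validate_clock_params(params)
  ov <- if (is.null(overrides)) mutant_overrides(genotype) else overrides
  if (!length(ov)) return(params)
  bad <- setdiff(names(ov), .param_names)
  if (length(bad))
    stop("unknown parameter symbol(s) in override: ",
         paste(bad, collapse = ", "), call. = FALSE)
  params[names(ov)] <- unlist(ov)
  validate_clock_params(params)
}

# ---------------------------------------------------------------------------
# Parameter file I/O

#' Read and write clock parameter files
#'
#' Flat key-value files hold one `symbol = value` pair per line (`#` starts a
#' comment); the two-column delimited form has columns `parameter` and
#' `value`. Both must cover valid symbols only; `read_clock_params()` fills
#' symbols missing from the file from `base`.
#'
#' @param path File path.
#' @param params A `clock_params` vector to write.
#' @param base Base set completed by the file's entries (default `"zero"`
#'   requires the file to be complete).
#' @param format `"keyvalue"` or `"table"` (comma-separated, header row).
#' @return `read_clock_params()`: a `clock_params` vector.
#' @export
read_clock_params <- function(path, base = "zero",
                              format = c("auto", "keyvalue", "table")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty parameter file: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("=", lines[[1]], fixed = TRUE)) "keyvalue" else "table"
  if (format == "keyvalue") {
    parts <- strsplit(lines, "=", fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("malformed line(s) in ", path,
           ": expected 'symbol = value'", call. = FALSE)
    syms <- trimws(vapply(parts, `[[`, "", 1L))
    vals <- suppressWarnings(as.numeric(trimws(vapply(parts, `[[`, "", 2L))))
  } else {
    tab <- utils::read.csv(text = lines, header = TRUE,
                           strip.white = TRUE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2)
      stop("parameter table needs two columns (parameter, value)",
           call. = FALSE)
    syms <- trimws(as.character(tab[[1]]))
    vals <- suppressWarnings(as.numeric(tab[[2]]))
  }
  bad <- setdiff(syms, .param_names)
  if (length(bad))
    stop("unknown parameter symbol(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyNA(vals))
    stop("non-numeric value(s) in ", path, " for: ",
         paste(syms[is.na(vals)], collapse = ", "), call. = FALSE)
  if (anyDuplicated(syms))
    stop("duplicated symbol(s) in ", path, call. = FALSE)
  p <- if (is.character(base)) clock_params(set = base) else
    validate_clock_params(base)
  p[syms] <- vals
  validate_clock_params(p)
}

#' @rdname read_clock_params
#' @export
write_clock_params <- function(params, path,
                               format = c("keyvalue", "table")) {
  format <- match.arg(format)
  params <- validate_clock_params(params)
  if (format == "keyvalue") {
    writeLines(sprintf("%s = %.17g", names(params), as.numeric(params)), path)
  } else {
    writeLines(c("parameter,value",
                 sprintf("%s,%.17g", names(params), as.numeric(params))),
               path)
  }
  invisible(path)
}

# Calibrated base sets are stored as plain-text key-value files under
# inst/extdata and loaded once at namespace load.
.param_sets <- new.env(parent = emptyenv())

.load_param_sets <- function() {
  dir <- system.file("extdata", package = "meclock")
  for (nm in c("wt_dd", "wt_ll")) {
    f <- file.path(dir, paste0("params_", nm, ".txt"))
    if (file.exists(f))
      assign(nm, read_clock_params(f, base = "zero"), envir = .param_sets)
  }
}
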