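#' @importFrom stats lm coef vcov rnorm sd median approx setNames fitted
#' @importFrom utils read.csv write.csv packageVersion modifyList
#' @importFrom minpack.lm nlsLM
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.conc_units <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)

#' Convert a concentration to molar
#'
#' All concentrations are stored internally in molar; user-facing arguments
#' carry explicit units (micromolar for DTNB, millimolar for coenzymes,
#' following bench convention). This helper performs the conversion and is
#' exported so callers can supply any of the recognised units.
#'
#' @param x numeric concentration value(s).
#' @param unit one of `"M"`, `"mM"`, `"uM"`, `"nM"`.
#' @return concentration in molar.
#' @examples
#' conc_to_molar(990, "uM")   # 9.9e-4 M
#' conc_to_molar(0.335, "mM") # 3.35e-4 M
#' @export
conc_to_molar <- function(x, unit = c("uM", "mM", "M", "nM")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(x))
  x * .conc_units[[unit]]
}

# Deterministic 31-polynomial rolling hash of a string, mod 2^31 - 1.
# Used to derive per-series child seeds from a master seed so that adding
# or removing one series never perturbs the noise draws of another.
string_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

child_seed <- function(master, key) {
  if (is.null(master)) return(NULL)
  as.integer((as.numeric(master) + string_hash(key)) %% 2147483647L)
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

# R-squared computed by hand so the zero-variance case (flat, perfectly
# fitted data) reports 1 instead of NaN.
r_squared <- function(observed, fitted) {
  tss <- sum((observed - mean(observed))^2)
  rss <- sum((observed - fitted)^2)
  if (tss <= 0) return(if (rss <= 1e-30) 1 else 0)
  max(0, min(1, 1 - rss / tss))
}

# vcov.lm warns on an essentially perfect fit; noiseless synthetic data is
# a designed use here, so silence that specific nuisance.
quiet_vcov <- function(fit) {
  withCallingHandlers(vcov(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

stop_shprotect <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "shprotect_error")))
}
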