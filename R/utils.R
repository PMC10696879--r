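#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix rowSums colSums t sparseMatrix readMM writeMM Diagonal
#' @importFrom stats glm binomial quasipoisson coef pchisq pnorm pt p.adjust
#'   kmeans dist rbinom rnorm rpois rnbinom runif rgamma plogis qlogis
#'   logLik predict var sd cor optim setNames complete.cases lm
#' @importFrom splines ns
#' @importFrom utils read.table write.table head
NULL

# one structured log line per pipeline stage; suppress with
# options(atacscreen.verbose = FALSE)
log_stage <- function(stage, ...) {
  if (!isTRUE(getOption("atacscreen.verbose", TRUE))) return(invisible(NULL))
  msg <- paste(..., sep = " ")
  message(sprintf("[%s] %s", stage, msg))
  invisible(NULL)
}

stop_field <- function(field, why) {
  stop(sprintf("invalid '%s': %s", field, why), call. = FALSE)
}

check_count <- function(x, field) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x))
    stop_field(field, "must be a single positive integer")
  as.integer(x)
}

check_prob <- function(x, field) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a probability in [0, 1]")
  as.numeric(x)
}

check_pos <- function(x, field) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x <= 0)
    stop_field(field, "must be a single positive number")
  as.numeric(x)
}

# dose log transform shared by the generator and the dose-response fits:
# d = log10(dose + delta), delta = smallest nonzero dose / 10, so vehicle
# (dose 0) enters as a finite low value
log_dose <- function(dose, delta = NULL) {
  if (is.null(delta)) {
    nz <- dose[dose > 0]
    if (length(nz) == 0) stop("no nonzero doses; cannot choose log offset")
    delta <- min(nz) / 10
  }
  list(d = log10(dose + delta), delta = delta)
}

as_dgc <- function(x) {
  methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}
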