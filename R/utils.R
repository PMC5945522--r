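#' @keywords internal
"_PACKAGE"

#' Class labels recognised by the pipeline
#'
#' Ordered disease states: healthy controls, then non-muscle-invasive
#' bladder cancer of low (G1+G2) and high (G3) grade, then muscle-invasive
#' disease. The ordering matters for trend tests.
#'
#' @export
BC_CLASSES <- c("control", "NMIBC_G1G2", "NMIBC_G3", "MIBC")

#' Smoking-status levels used as adjustment covariates
#' @export
SMOKING_LEVELS <- c("never", "former", "current")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# `seed = NULL` leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Stop with a consistent error class so callers/tests can distinguish
# user-input problems from programming errors.
input_error <- function(msg, class = "urimir_input_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
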