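#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx cor.test fisher.test kmeans prcomp rbinom rnorm
#'   runif sd setNames aggregate complete.cases
#' @importFrom utils read.csv write.csv head packageVersion
#' @importFrom grDevices hcl.colors
#' @importFrom graphics matplot legend abline axis
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("domsuite_validation_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("domsuite_format_error", "error")))
}

stop_unmeasurable <- function(...) {
  stop(errorCondition(paste0(...), class = c("domsuite_unmeasurable_error", "error")))
}
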