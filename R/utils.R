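#' @keywords internal
"_PACKAGE"

# Shared argument checks. All user-facing validation errors go through
# stop_invalid() so callers can rely on the "uprflow_invalid" condition class.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("uprflow_invalid", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("uprflow_degenerate", "error")))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(name, " must be a single finite number")
  }
  if (x < lower || x > upper) {
    stop_invalid(name, " must be in [", lower, ", ", upper, "], got ", x)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop_invalid(name, " must be an integer >= ", min)
  }
  as.integer(x)
}

#' Derive a per-stage seed from a single root seed
#'
#' Every source of randomness in the package flows from one root seed; each
#' pipeline stage draws its own seed deterministically from it so that stages
#' can be re-run individually with identical results.
#'
#' @param root_seed single integer root seed.
#' @param stage integer stage index (>= 0).
#' @return an integer seed in \[0, 2^31).
#' @export
derive_seed <- function(root_seed, stage) {
  root_seed <- check_count(root_seed, "root_seed", min = 0L)
  stage <- check_count(stage, "stage", min = 0L)
  # affine hash mod the Mersenne prime 2^31 - 1; keeps seeds in 32-bit range
  as.integer((as.numeric(root_seed) * 48271 + as.numeric(stage) * 7919 + 1) %% 2147483647)
}

# condition levels used throughout: wild type plus three constitutive timepoints
UPR_CONDITIONS <- c("WT", "CA1", "CA2", "CA3")

#' Standard 3-replicate x 4-condition array design
#'
#' The default layout of the study design this package emulates: independent
#' biological triplicates of a wild-type strain (WT) and of a constitutively
#' activated strain sampled at three timepoints (CA1, CA2, CA3) -- 12 arrays.
#'
#' @param n_replicates replicates per condition (default 3).
#' @param conditions character vector of condition labels.
#' @return a `data.frame` with columns `array_id`, `condition`, `replicate`.
#' @examples
#' default_design()
#' @export
default_design <- function(n_replicates = 3L, conditions = UPR_CONDITIONS) {
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (length(conditions) < 1L) stop_invalid("at least one condition required")
  data.frame(
    array_id = paste0(rep(conditions, each = n_replicates), "_r",
                      rep(seq_len(n_replicates), times = length(conditions))),
    condition = rep(conditions, each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = length(conditions)),
    stringsAsFactors = FALSE
  )
}

check_design <- function(design) {
  if (!is.data.frame(design) ||
      !all(c("array_id", "condition", "replicate") %in% names(design))) {
    stop_invalid("design must be a data.frame with array_id, condition, replicate")
  }
  if (anyDuplicated(design$array_id)) stop_invalid("duplicate array_id in design")
  key <- paste(design$condition, design$replicate)
  if (anyDuplicated(key)) stop_invalid("replicate ids must be unique within condition")
  invisible(design)
}
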