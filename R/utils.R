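# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library functions never perturb a user's
# simulation.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_param <- function(...) stop(..., call. = FALSE)

check_scalar_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop_param(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x) || x <= 0) {
    stop_param(sprintf("`%s` must be a single strictly positive finite number", name))
  }
  as.numeric(x)
}

#' @importFrom stats aggregate prcomp quantile rbinom rgamma rlnorm
#'   t.test pgamma ks.test plogis predict sd setNames
NULL

# Columns every stimulation table must carry, in canonical order.
STIM_COLUMNS <- c("subject_id", "session_id", "group", "isi_ms", "amplitude_uv")

check_stim_table <- function(x, require = STIM_COLUMNS) {
  if (!is.data.frame(x)) {
    stop_param("expected a data.frame conforming to the stimulation schema")
  }
  missing <- setdiff(require, names(x))
  if (length(missing)) {
    stop_param(
      "stimulation table is missing required column(s): ",
      paste(missing, collapse = ", ")
    )
  }
  invisible(x)
}
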