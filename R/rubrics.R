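#' Load a diet scoring rubric
#'
#' Rubrics are human-editable YAML files declaring, for each component of a
#' dietary pattern score, its source column, direction
#' (beneficial / detrimental / moderate) and scoring rule.  Three rubrics are
#' shipped with the package: `MDS` (9 components, within-sample median
#' splits), `MIND` (15 components, three-level cutoff scoring) and `AHEI`
#' (11 components, proportional 0-10 anchors).  Serving cutoffs and anchors
#' are transcribed from the published instruments and are data, not code:
#' point `path` at an edited copy to match a cohort's own implementation.
#'
#' @param instrument one of `"MDS"`, `"MIND"`, `"AHEI"` (ignored when `path`
#'   is given).
#' @param path optional path to a rubric YAML file.
#' @return a `diet_rubric` object: a list with `instrument`, `version` and a
#'   list of validated `components`.
#' @export
#' @examples
#' r <- load_rubric("MIND")
#' length(r$components)  # 15
load_rubric <- function(instrument = c("MDS", "MIND", "AHEI"), path = NULL) {
  if (is.null(path)) {
    instrument <- match.arg(instrument)
    path <- system.file("extdata", "rubrics",
                        paste0(tolower(instrument), ".yaml"),
                        package = "dietmetab", mustWork = TRUE)
  }
  rubric <- yaml::read_yaml(path)
  validate_rubric(rubric)
}

validate_rubric <- function(rubric) {
  if (is.null(rubric$instrument) || is.null(rubric$components)) {
    stop_dm("rubric must declare 'instrument' and 'components'")
  }
  n_expected <- c(MDS = 9L, MIND = 15L, AHEI = 11L)[[rubric$instrument]]
  if (!is.null(n_expected) && length(rubric$components) != n_expected) {
    stop_dm(sprintf("%s rubric must have %d components, found %d",
                    rubric$instrument, n_expected, length(rubric$components)))
  }
  for (comp in rubric$components) {
    if (is.null(comp$name) || is.null(comp$column) || is.null(comp$rule)) {
      stop_dm("every rubric component needs 'name', 'column' and 'rule'")
    }
    if (identical(comp$rule, "three_level")) {
      lo <- min(comp$half_cutoff, comp$full_cutoff)
      hi <- max(comp$half_cutoff, comp$full_cutoff)
      if (is.na(lo) || is.na(hi) || lo > hi) {
        stop_dm(sprintf("component '%s': cutoffs must be ordered numbers",
                        comp$name))
      }
      ord <- if (identical(comp$direction, "detrimental")) {
        comp$full_cutoff <= comp$half_cutoff
      } else {
        comp$half_cutoff <= comp$full_cutoff
      }
      if (!ord) {
        stop_dm(sprintf(
          "component '%s': cutoffs not monotone for direction '%s'",
          comp$name, comp$direction))
      }
    }
    if (identical(comp$rule, "proportional")) {
      az <- comp$anchor_zero
      af <- comp$anchor_full
      scal <- function(a) if (is.list(a)) unlist(a) else a
      if (any(scal(az) == scal(af))) {
        stop_dm(sprintf("component '%s': anchor_zero == anchor_full",
                        comp$name))
      }
    }
    if (identical(comp$rule, "three_level_window")) {
      if (length(comp$half_range) != 2L || length(comp$full_range) != 2L ||
          comp$half_range[1] > comp$half_range[2] ||
          comp$full_range[1] > comp$full_range[2]) {
        stop_dm(sprintf("component '%s': malformed window ranges", comp$name))
      }
    }
  }
  class(rubric) <- "diet_rubric"
  rubric
}

#' @export
print.diet_rubric <- function(x, ...) {
  cat(sprintf("<diet_rubric> %s (version %s), %d components\n",
              x$instrument, x$version %||% "?", length(x$components)))
  for (comp in x$components) {
    cat(sprintf("  %-24s %-12s %s [%s]\n", comp$name, comp$direction,
                comp$rule, comp$column))
  }
  invisible(x)
}

#' Load the three default rubrics at once
#'
#' @return named list with elements `MDS`, `MIND`, `AHEI`.
#' @export
default_rubrics <- function() {
  list(MDS = load_rubric("MDS"), MIND = load_rubric("MIND"),
       AHEI = load_rubric("AHEI"))
}

#' Build an extreme-adherence intake profile from a rubric
#'
#' Constructs a single intake row that attains full credit (or zero credit)
#' on every component of a MIND or AHEI rubric — at or beyond the
#' full-credit cutoff/anchor for beneficial components, at zero (or at the
#' zero anchor) for detrimental ones, and inside (or outside) the moderate
#' window for alcohol/wine.  Median-split components (MDS) have no absolute
#' extreme and are set to zero; use a dominance construction for MDS
#' extremes.  Useful for auditing an edited rubric's attainable range.
#'
#' @param rubric a `diet_rubric`.
#' @param credit `"full"` or `"zero"`.
#' @param sex sex level used to resolve sex-specific cutoffs.
#' @return one-row data.frame with one column per rubric source column.
#' @export
extreme_profile <- function(rubric, credit = c("full", "zero"),
                            sex = "female") {
  credit <- match.arg(credit)
  row <- list()
  for (comp in rubric$components) {
    detr <- identical(comp$direction, "detrimental")
    val <- switch(
      comp$rule,
      three_level = if (credit == "full") {
        if (detr) 0 else max(comp$full_cutoff, comp$half_cutoff) + 1
      } else {
        if (detr) max(comp$full_cutoff, comp$half_cutoff) + 1 else 0
      },
      three_level_window = if (credit == "full") {
        mean(unlist(comp$full_range))
      } else {
        max(unlist(comp$full_range), unlist(comp$half_range)) + 10
      },
      proportional = {
        anchor <- if (credit == "full") comp$anchor_full else
          comp$anchor_zero
        resolve_by_sex(anchor, sex, comp$name)
      },
      moderate_window = {
        win <- vapply(c(1L, 2L), function(i)
          resolve_by_sex(lapply(comp$window, `[[`, i), sex, comp$name),
          numeric(1L))
        if (credit == "full") {
          mean(win)
        } else if (!is.null(comp$zero_anchor)) {
          resolve_by_sex(comp$zero_anchor, sex, comp$name)
        } else {
          2 * win[2L] + 10
        }
      },
      median_split = 0)
    row[[comp$column]] <- val
  }
  as.data.frame(row, check.names = FALSE)
}
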