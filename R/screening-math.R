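#' Screening performance of a diagnostic method
#'
#' A (sensitivity, specificity) pair in \[0,1\] with a method label;
#' the unit composed by [net_serial()] and [net_parallel()].
#'
#' @param sensitivity,specificity Proportions in \[0,1\].
#' @param label Method name.
#' @return List of class `"screening_performance"`.
#' @examples
#' screening_performance(0.80, 0.89, "HAIR")
#' @export
screening_performance <- function(sensitivity, specificity, label = "") {
  if (length(sensitivity) != 1L || length(specificity) != 1L ||
      is.na(sensitivity) || is.na(specificity) ||
      sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    stop("sensitivity and specificity must be single values in [0, 1]")
  }
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 label = label),
            class = "screening_performance")
}

#' @export
print.screening_performance <- function(x, ...) {
  cat(sprintf("%s: sensitivity %.4f, specificity %.4f\n",
              if (nzchar(x$label)) x$label else "method",
              x$sensitivity, x$specificity))
  invisible(x)
}

check_perf_list <- function(perfs) {
  if (!is.list(perfs) || length(perfs) < 2L) {
    stop("need at least two screening performances to compose")
  }
  lapply(perfs, function(p) {
    if (!inherits(p, "screening_performance")) {
      stop("every element must be a screening_performance")
    }
  })
  invisible(perfs)
}

#' Net performance of a serial (all-positive, AND) combination
#'
#' Declaring disease only when every method is positive multiplies the
#' sensitivities and compounds the specificities:
#' `SE = prod(SE_i)`, `SP = 1 - prod(1 - SP_i)` — the pairwise rules
#' `SE1*SE2` and `SP1 + SP2 - SP1*SP2` folded associatively over k methods.
#' Net sensitivity never exceeds the weakest method's; net specificity never
#' falls below the strongest method's. Independence of the methods'
#' errors conditional on disease status is assumed.
#'
#' @param perfs List of [screening_performance()] objects (length >= 2).
#' @return A `screening_performance` labelled `"serial(...)"`.
#' @examples
#' net_serial(list(screening_performance(0.80, 0.89, "HAIR"),
#'                 screening_performance(0.76, 0.66, "Gholam"),
#'                 screening_performance(0.595, 0.327, "LFS")))
#' @export
net_serial <- function(perfs) {
  check_perf_list(perfs)
  se <- prod(vapply(perfs, `[[`, numeric(1), "sensitivity"))
  sp <- 1 - prod(1 - vapply(perfs, `[[`, numeric(1), "specificity"))
  screening_performance(se, sp, paste0(
    "serial(", paste(vapply(perfs, `[[`, character(1), "label"),
                     collapse = ","), ")"))
}

#' Net performance of a parallel (any-positive, OR) combination
#'
#' Declaring disease when at least one method is positive compounds the
#' sensitivities and multiplies the specificities:
#' `SE = 1 - prod(1 - SE_i)`, `SP = prod(SP_i)`. Net sensitivity never falls
#' below the strongest method's; net specificity never exceeds the weakest
#' method's.
#'
#' @inheritParams net_serial
#' @return A `screening_performance` labelled `"parallel(...)"`.
#' @export
net_parallel <- function(perfs) {
  check_perf_list(perfs)
  se <- 1 - prod(1 - vapply(perfs, `[[`, numeric(1), "sensitivity"))
  sp <- prod(vapply(perfs, `[[`, numeric(1), "specificity"))
  screening_performance(se, sp, paste0(
    "parallel(", paste(vapply(perfs, `[[`, character(1), "label"),
                       collapse = ","), ")"))
}

#' Published single-method performances of the three NASH scores
#'
#' The validation-study sensitivities and specificities: HAIR 0.80/0.89,
#' Gholam 0.76/0.66, and the NASH liver fat score in its two validation
#' populations — Finnish 0.595/0.797, Italian 0.929/0.327. `lfs_variant`
#' selects which liver-fat-score validation enters the panel.
#'
#' @param lfs_variant `"finnish"` or `"italian"`.
#' @return List of three [screening_performance()] objects.
#' @export
published_performances <- function(lfs_variant = c("finnish", "italian")) {
  lfs_variant <- match.arg(lfs_variant)
  lfs <- if (lfs_variant == "finnish") {
    screening_performance(0.595, 0.797, "LFS")
  } else {
    screening_performance(0.929, 0.327, "LFS")
  }
  list(screening_performance(0.80, 0.89, "HAIR"),
       screening_performance(0.76, 0.66, "Gholam"),
       lfs)
}

#' Net-performance table for the combined classifications
#'
#' Tabulates each single method and the serial/parallel combinations under
#' both liver-fat-score validation variants.
#'
#' @param path Optional TSV output path.
#' @return data.frame with columns `combination`, `lfs_variant`,
#'   `sensitivity`, `specificity`.
#' @export
net_performance_table <- function(path = NULL) {
  rows <- list()
  for (v in c("finnish", "italian")) {
    perfs <- published_performances(v)
    for (p in perfs) {
      rows[[length(rows) + 1L]] <- data.frame(
        combination = p$label, lfs_variant = v,
        sensitivity = p$sensitivity, specificity = p$specificity)
    }
    ser <- net_serial(perfs); par <- net_parallel(perfs)
    rows[[length(rows) + 1L]] <- data.frame(
      combination = "all3_serial", lfs_variant = v,
      sensitivity = ser$sensitivity, specificity = ser$specificity)
    rows[[length(rows) + 1L]] <- data.frame(
      combination = "any1_parallel", lfs_variant = v,
      sensitivity = par$sensitivity, specificity = par$specificity)
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}
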