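#' Sequential (Type-I) ANOVA with numeric design predictors
#'
#' Ordinary least squares of the response on the raw (uncentered) numeric
#' predictors and their interactions, with F-tests from sequential sums of
#' squares in the stated term order. Because the predictors enter as numeric
#' covariates, every term carries 1 numerator degree of freedom and the
#' denominator df is \code{n - n_terms - 1}. Raw numeric interactions are not
#' orthogonal, so the term order matters and is preserved exactly as given.
#'
#' @param table Data frame of run rows.
#' @param response Name of the response column.
#' @param predictors Character vector of main-effect columns, in entry order.
#' @param interaction_order Highest interaction order to include (default:
#'   all, up to \code{length(predictors)}). Terms are ordered as all main
#'   effects, then all two-way interactions, and so on, each block in the
#'   combinatorial order of the predictors.
#' @return Object of class \code{"seq_anova"}: a data.frame with columns
#'   \code{term}, \code{df_num}, \code{df_den}, \code{ss}, \code{F}, \code{p},
#'   plus attributes \code{rss} (residual SS) and \code{tss} (total SS).
#' @export
sequential_anova <- function(table, response, predictors,
                             interaction_order = length(predictors)) {
  stopifnot(is.data.frame(table), response %in% names(table))
  if (!all(predictors %in% names(table))) {
    stop("missing predictor column(s): ",
         paste(setdiff(predictors, names(table)), collapse = ", "))
  }
  for (col in c(response, predictors)) {
    if (!is.numeric(table[[col]])) stop("column '", col, "' must be numeric")
  }
  terms_list <- .anova_terms(predictors, interaction_order)
  labels <- vapply(terms_list, paste, character(1), collapse = ":")
  n <- nrow(table)
  df_den <- n - length(terms_list) - 1L
  if (df_den < 1L) stop("too few rows (", n, ") for ", length(terms_list),
                        " terms")

  # ordinary lm() fit with the terms entered in the stated order; anova()
  # then yields the sequential (Type-I) sums of squares in exactly that order
  fml <- stats::reformulate(labels, response = response)
  fml <- stats::terms(fml, keep.order = TRUE)
  fit <- stats::lm(fml, data = table)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop("rank-deficient design: term(s) ", paste(bad, collapse = ", "),
         " are collinear with earlier columns")
  }
  # degenerate (perfect-fit) cases are handled explicitly below
  an <- suppressWarnings(stats::anova(fit))
  stopifnot(all(an$Df[seq_along(labels)] == 1L),
            an$Df[length(labels) + 1L] == df_den)
  seq_ss <- an$`Sum Sq`[seq_along(labels)]
  rss <- an$`Sum Sq`[length(labels) + 1L]

  y <- table[[response]]
  tss <- sum((y - mean(y))^2)
  if (tss <= 1e-12 * n * max(1, mean(y)^2)) {
    # constant response: no variance to attribute
    Fv <- rep(0, length(seq_ss)); pv <- rep(1, length(seq_ss))
  } else if (rss <= 1e-10 * tss) {
    # numerically exact fit: terms carrying signal blow up, the rest vanish
    Fv <- ifelse(seq_ss > 1e-10 * tss, Inf, 0)
    pv <- ifelse(is.infinite(Fv), 0, 1)
  } else {
    Fv <- seq_ss / (rss / df_den)
    pv <- stats::pf(Fv, 1, df_den, lower.tail = FALSE)
  }

  out <- data.frame(term = labels, df_num = 1L, df_den = df_den,
                    ss = seq_ss, F = Fv, p = pv, stringsAsFactors = FALSE)
  attr(out, "rss") <- rss
  attr(out, "tss") <- tss
  class(out) <- c("seq_anova", "data.frame")
  out
}

# main effects, then two-way, three-way, ... interactions, each block in the
# product-expansion order of p1*p2*...*pk (the order the printed tables use)
.anova_terms <- function(predictors, interaction_order) {
  stopifnot(interaction_order >= 1)
  if (length(predictors) == 1L) return(list(predictors))
  fml <- stats::reformulate(paste(predictors, collapse = "*"))
  labels <- attr(stats::terms(fml), "term.labels")
  terms_list <- strsplit(labels, ":", fixed = TRUE)
  keep <- lengths(terms_list) <= interaction_order
  terms_list[keep]
}

#' @export
print.seq_anova <- function(x, ...) {
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, 6)
  df$F <- signif(df$F, 5)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Propagule-stage ANOVA tables
#'
#' Sequential ANOVAs of the three propagule-stage responses (total mass,
#' number, and mean mass of the surviving propagules per parent) on parental
#' nitrogen, survival rate and their interaction, in that order. With the
#' default 120-run design each table has denominator df 116.
#'
#' @param runs Output of [run_propagule_factorial()].
#' @return Named list of three \code{"seq_anova"} tables:
#'   \code{total_propagule_mass}, \code{n_survivors},
#'   \code{mean_propagule_mass}.
#' @export
table2_anova <- function(runs) {
  responses <- c("total_propagule_mass", "n_survivors", "mean_propagule_mass")
  stats::setNames(lapply(responses, function(resp) {
    sequential_anova(runs, resp, c("PN", "SR"))
  }), responses)
}

#' Offspring-generation ANOVA tables
#'
#' Sequential ANOVAs of the summed and the mean final mass of surviving
#' clonal offspring on parental N, offspring N, survival rate and
#' developmental time, with all interactions up to the four-way term (15
#' terms). With the default 4320-run factorial each table has denominator
#' df 4304.
#'
#' @param runs Output of [run_full_factorial()].
#' @return Named list of two \code{"seq_anova"} tables:
#'   \code{summed_offspring_mass}, \code{mean_offspring_mass}.
#' @export
table3_anova <- function(runs) {
  responses <- c("summed_offspring_mass", "mean_offspring_mass")
  stats::setNames(lapply(responses, function(resp) {
    sequential_anova(runs, resp, c("PN", "ON", "SR", "T"))
  }), responses)
}

#' Aggregated figure summaries
#'
#' Per-cell means and standard errors (sd/sqrt(replicates)) over replicate
#' runs: the propagule-stage summary aggregates over the PN x SR grid; the
#' offspring-stage summaries aggregate the 100%-survival subset over the
#' PN x ON grid separately for each developmental time.
#'
#' @param propagule_runs Output of [run_propagule_factorial()] (or NULL).
#' @param full_runs Output of [run_full_factorial()] (or NULL).
#' @return Named list of data.frames: \code{propagule} (PN, SR, and
#'   mean/se of total mass, number and mean mass) and \code{offspring}
#'   (T, PN, ON, and mean/se of summed and mean offspring mass, SR = 1
#'   subset). Empty inputs yield empty data.frames with headers.
#' @export
summarize_figures <- function(propagule_runs = NULL, full_runs = NULL) {
  out <- list()
  if (!is.null(propagule_runs)) {
    out$propagule <- .cell_summary(
      propagule_runs, c("PN", "SR"),
      c("total_propagule_mass", "n_survivors", "mean_propagule_mass"))
  }
  if (!is.null(full_runs)) {
    sub <- full_runs[full_runs$SR == 1, , drop = FALSE]
    out$offspring <- .cell_summary(
      sub, c("T", "PN", "ON"),
      c("summed_offspring_mass", "mean_offspring_mass"))
  }
  out
}

.cell_summary <- function(runs, by, responses) {
  cols <- unlist(lapply(responses, function(r) paste0(r, c("_mean", "_se"))))
  if (is.null(runs) || nrow(runs) == 0L) {
    empty <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(by) + length(cols)), c(by, cols)))
    return(empty)
  }
  key <- interaction(runs[by], drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(runs, key), function(cell) {
    row <- cell[1, by, drop = FALSE]
    for (r in responses) {
      row[[paste0(r, "_mean")]] <- mean(cell[[r]])
      row[[paste0(r, "_se")]] <- stats::sd(cell[[r]]) / sqrt(nrow(cell))
    }
    row
  })
  out <- do.call(rbind, pieces)
  out <- out[do.call(order, out[by]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
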