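#' Repeated-measures ANOVA with sphericity handling
#'
#' Univariate repeated-measures ANOVA for balanced fully-within-subject
#' designs with one to three factors. Replicate observations are averaged to
#' one cell mean per subject and condition; each effect is tested against
#' its own subject-by-effect interaction. For effects with more than one
#' numerator degree of freedom, sphericity is checked with Mauchly's test on
#' the orthonormal-contrast covariance matrix and, when violated at p < .05,
#' both degrees of freedom are multiplied by the Greenhouse-Geisser epsilon
#' before recomputing the p value. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data A long data frame.
#' @param dv Name of the numeric dependent-variable column.
#' @param within Character vector (length 1-3) of within-subject factor
#'   columns.
#' @param subject Name of the subject identifier column.
#' @return A tibble of class `segmot_anova`, one row per effect: `term`,
#'   `df_num`, `df_den` (after any correction), `statistic` (F), `p.value`,
#'   `partial_eta_sq`, `gg_epsilon`, `mauchly_p`, `corrected`.
#' @examples
#' set.seed(1)
#' d <- expand.grid(subj = paste0("s", 1:5), cond = c("a", "b", "c"))
#' d$y <- rnorm(nrow(d)) + as.integer(d$cond)
#' rm_anova(d, dv = "y", within = "cond", subject = "subj")
#' @export
rm_anova <- function(data, dv, within, subject) {
  cols <- c(subject, within, dv)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) abort(paste0("missing columns: ", toString(miss)))
  if (length(within) < 1 || length(within) > 3) {
    abort("`within` must name 1 to 3 factors.")
  }
  d <- tibble::as_tibble(data)[, cols]
  d[[subject]] <- factor(d[[subject]])
  for (w in within) d[[w]] <- factor(d[[w]])
  if (!is.numeric(d[[dv]])) abort("`dv` must be numeric.")

  agg <- d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(subject, within)))) |>
    dplyr::summarise(.dv = mean(.data[[dv]]), .groups = "drop")
  full <- tidyr::complete(agg, !!!syms(c(subject, within)))
  if (anyNA(full$.dv)) {
    bad <- full[is.na(full$.dv), c(subject, within)]
    cell <- paste(unlist(bad[1, ]), collapse = " / ")
    abort(sprintf("design is unbalanced: no observation for cell %s (and %d more).",
                  cell, nrow(bad) - 1L))
  }
  n_subj <- nlevels(full[[subject]])
  if (n_subj < 2) abort("need at least 2 subjects.")

  f <- as.formula(paste(".dv ~", paste(c(subject, within), collapse = " * ")))
  # replicate averaging saturates the model (0-df residual); the effect and
  # error strata used below are unaffected, so silence lm's perfect-fit note
  at <- withCallingHandlers(
    anova(lm(f, data = full)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  term_sets <- strsplit(rownames(at), ":", fixed = TRUE)
  find_term <- function(set) {
    hit <- which(vapply(term_sets, function(ts) setequal(ts, set), logical(1)))
    if (length(hit) != 1) abort("internal error: ANOVA term lookup failed.")
    hit
  }

  effects <- unlist(lapply(seq_along(within), function(k) {
    utils::combn(within, k, simplify = FALSE)
  }), recursive = FALSE)

  rows <- lapply(effects, function(e) {
    ie <- find_term(e)
    ier <- find_term(c(subject, e))
    ss_e <- at[ie, "Sum Sq"]
    df_e <- at[ie, "Df"]
    ss_r <- at[ier, "Sum Sq"]
    df_r <- at[ier, "Df"]
    fval <- (ss_e / df_e) / (ss_r / df_r)
    eps <- NA_real_
    mau_p <- NA_real_
    if (df_e >= 2) {
      sph <- sphericity_stats(full, subject, e)
      eps <- sph$epsilon
      mau_p <- sph$mauchly_p
    }
    corrected <- !is.na(mau_p) && mau_p < 0.05
    df_num <- if (corrected) df_e * eps else df_e
    df_den <- if (corrected) df_r * eps else df_r
    tibble::tibble(
      term = paste(e, collapse = ":"),
      df_num = df_num, df_den = df_den,
      statistic = fval,
      p.value = pf(fval, df_num, df_den, lower.tail = FALSE),
      partial_eta_sq = ss_e / (ss_e + ss_r),
      gg_epsilon = eps, mauchly_p = mau_p, corrected = corrected
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("segmot_anova", class(out))
  attr(out, "n_subjects") <- n_subj
  attr(out, "dv") <- dv
  out
}

# Greenhouse-Geisser epsilon and Mauchly's test for one within effect,
# computed from per-subject scores on orthonormal effect contrasts.
sphericity_stats <- function(full, subject, effect) {
  cell <- full |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(subject, effect)))) |>
    dplyr::summarise(.dv = mean(.data$.dv), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(subject, effect))))
  n_subj <- nlevels(cell[[subject]])
  n_cells <- nrow(cell) / n_subj
  # rows sorted subject-slowest, then effect factors: first effect factor
  # varies slowest within subject, matching the Kronecker contrast order
  Y <- matrix(cell$.dv, nrow = n_subj, ncol = n_cells, byrow = TRUE)
  C <- Reduce(kronecker, lapply(effect, function(w) {
    k <- nlevels(cell[[w]])
    cc <- contr.helmert(k)
    sweep(cc, 2, sqrt(colSums(cc^2)), "/")
  }))
  scores <- Y %*% C
  S <- cov(scores)
  p <- ncol(S)
  epsilon <- sum(diag(S))^2 / (p * sum(S^2))
  mauchly_p <- NA_real_
  dets <- det(S)
  if (n_subj - 1 >= p && is.finite(dets) && dets > 0) {
    W <- dets / (sum(diag(S)) / p)^p
    nd <- n_subj - 1
    cc <- 1 - (2 * p^2 + p + 2) / (6 * p * nd)
    chi <- -nd * cc * log(W)
    dfm <- p * (p + 1) / 2 - 1
    mauchly_p <- pchisq(chi, dfm, lower.tail = FALSE)
  }
  list(epsilon = epsilon, mauchly_p = mauchly_p)
}

#' @export
print.segmot_anova <- function(x, ...) {
  cat(sprintf("<segmot RM-ANOVA> %d subject(s), dv = %s\n",
              attr(x, "n_subjects"), attr(x, "dv")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @export
tidy.segmot_anova <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.segmot_anova <- function(x, ...) {
  tibble::tibble(n_subjects = attr(x, "n_subjects"),
                 n_effects = nrow(x),
                 any_corrected = any(x$corrected))
}
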