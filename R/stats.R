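# Statistical summaries of generation durations: factorial ANOVA with
# backward stepwise removal, assumption checks, Tukey comparisons within
# province, and jackknife SE of the mean generation time.

#' Stepwise factorial ANOVA of generation durations
#'
#' Fits the full model with all two-way interactions among the supplied
#' factors, then removes non-significant terms backwards, one at a time:
#' at each step the eligible term (interactions are always eligible before
#' the main effects marginal to them) with the highest F-test p-value is
#' dropped if p >= alpha, and the model refitted, until every retained
#' term is significant. Sequential (type I) sums of squares are reported
#' for the final model, matching `aov`; with unbalanced data the order of
#' terms therefore matters and is the order given in `factors`. Residual
#' normality (Shapiro-Wilk) and homoscedasticity across retained-factor
#' cells (Bartlett) are checked on the final fit.
#'
#' Completely aliased terms (e.g. a factor nested inside another) are
#' dropped before selection with a warning, or abort with an error naming
#' them when `on_alias = "error"`.
#'
#' @param records Data frame with a `duration_dd` column and the factor
#'   columns (typically from [duration_table()]).
#' @param factors Character vector of factor column names to analyse.
#' @param alpha Removal threshold (default 0.05).
#' @param on_alias `"drop"` (default) or `"error"` for confounded terms.
#' @return Object of class `anova_stepwise` with elements `table`
#'   (per-term F, df, p for retained terms), `removed` (term and p at
#'   removal), `aliased`, `shapiro_p`, `bartlett_p`, `fit`.
#' @export
anova_stepwise <- function(records,
                           factors = c("province", "area", "year",
                                       "flight_order"),
                           alpha = 0.05, on_alias = c("drop", "error")) {
  on_alias <- match.arg(on_alias)
  stopifnot(nrow(records) > 0, "duration_dd" %in% names(records))
  factors <- intersect(factors, names(records))
  dat <- records
  for (f in factors) dat[[f]] <- factor(dat[[f]])
  # factors with a single level carry no information
  factors <- factors[vapply(dat[factors], nlevels, integer(1)) >= 2L]
  if (!length(factors)) stop("anova_stepwise: no factor has >= 2 levels")
  form <- stats::as.formula(paste(
    "duration_dd ~ (", paste(factors, collapse = " + "), ")^2"))
  fit <- stats::aov(form, data = dat)

  # fully aliased terms contribute no estimable column (zero df)
  aliased <- character(0)
  tl <- attr(stats::terms(fit), "term.labels")
  asgn <- fit$assign[fit$qr$pivot[seq_len(fit$qr$rank)]]
  zero_df <- setdiff(seq_along(tl), asgn)
  if (length(zero_df)) {
    aliased <- tl[zero_df]
    msg <- paste("aliased (confounded) terms:", paste(aliased, collapse = ", "))
    if (on_alias == "error")
      stop(structure(class = c("ddphen_aliased", "error", "condition"),
                     list(message = msg, call = sys.call())))
    warning(msg, "; dropped before selection", call. = FALSE)
    form <- stats::update(form, paste(". ~ . -", paste(aliased, collapse = " - ")))
    fit <- stats::aov(form, data = dat)
  }

  removed <- data.frame(term = character(0), p_at_removal = numeric(0))
  repeat {
    d1 <- stats::drop1(fit, test = "F")
    terms_now <- rownames(d1)[-1L]
    if (!length(terms_now)) break
    p <- d1$`Pr(>F)`[-1L]
    # terms aliased within the current fit (0 df) are removed first
    df0 <- d1$Df[-1L] == 0
    if (any(df0)) {
      worst <- terms_now[which(df0)[1L]]; worst_p <- NA_real_
    } else if (max(p, na.rm = TRUE) >= alpha) {
      i <- which.max(p)
      worst <- terms_now[i]; worst_p <- p[i]
    } else break
    removed <- rbind(removed,
                     data.frame(term = worst, p_at_removal = worst_p))
    form <- stats::update(form, paste(". ~ . -", worst))
    if (length(attr(stats::terms(form), "term.labels")) == 0L) {
      fit <- stats::aov(stats::update(form, . ~ 1), data = dat)
      break
    }
    fit <- stats::aov(form, data = dat)
  }

  retained <- attr(stats::terms(fit), "term.labels")
  tab <- if (length(retained)) {
    a <- summary(fit)[[1L]]
    rn <- trimws(rownames(a))
    keep <- rn != "Residuals"
    data.frame(term = rn[keep], df_num = a$Df[keep],
               df_den = a$Df[!keep], F = a$`F value`[keep],
               p = a$`Pr(>F)`[keep])
  } else {
    data.frame(term = character(0), df_num = integer(0),
               df_den = integer(0), F = numeric(0), p = numeric(0))
  }

  res <- stats::residuals(fit)
  shapiro_p <- if (length(res) >= 3 && stats::sd(res) > 0)
    stats::shapiro.test(res)$p.value else NA_real_
  bart_p <- NA_real_
  ret_main <- intersect(retained, factors)
  if (length(ret_main)) {
    cells <- interaction(dat[ret_main], drop = TRUE)
    sizes <- table(cells)
    if (sum(sizes >= 2L) >= 2L) {
      ok <- dat[cells %in% names(sizes)[sizes >= 2L], , drop = FALSE]
      cells_ok <- droplevels(interaction(ok[ret_main], drop = TRUE))
      v <- tapply(ok$duration_dd, cells_ok, stats::var)
      if (all(v > 0, na.rm = TRUE))
        bart_p <- stats::bartlett.test(ok$duration_dd, cells_ok)$p.value
    }
  }

  structure(list(table = tab, removed = removed, aliased = aliased,
                 shapiro_p = shapiro_p, bartlett_p = bart_p,
                 alpha = alpha, fit = fit),
            class = "anova_stepwise")
}

#' @export
print.anova_stepwise <- function(x, ...) {
  cat("Stepwise ANOVA (alpha =", x$alpha, ")\n")
  if (nrow(x$table)) {
    cat("Retained terms:\n")
    print(transform(x$table, F = round(F, 3), p = signif(p, 3)),
          row.names = FALSE)
  } else cat("No terms retained.\n")
  if (nrow(x$removed))
    cat("Removed:", paste(x$removed$term, collapse = ", "), "\n")
  if (length(x$aliased))
    cat("Aliased:", paste(x$aliased, collapse = ", "), "\n")
  cat(sprintf("Shapiro-Wilk p = %.3g; Bartlett p = %.3g\n",
              x$shapiro_p, x$bartlett_p))
  invisible(x)
}

#' Tukey multiple comparisons of flight duration within one province
#'
#' All pairwise comparisons of mean generation duration between seasonal
#' flight orders, using the studentized range distribution at `alpha`
#' (Tukey-Kramer standard errors for unequal group sizes), followed by a
#' compact letter display: levels sharing a letter are not significantly
#' different. Letters come from a deterministic greedy insert-absorb pass
#' over the significance matrix. Flight orders with fewer than two
#' observations are excluded with a warning.
#'
#' @param records Duration records (see [duration_table()]).
#' @param province Province to subset.
#' @param alpha Familywise significance level (default 0.05).
#' @return Object of class `tukey_groups`: data frame with `flight_order`,
#'   `n`, `mean_dd`, `se_dd`, `letters`; attribute `pairwise` (matrix of
#'   adjusted p-values).
#' @export
tukey_by_province <- function(records, province, alpha = 0.05) {
  d <- records[records$province == province, , drop = FALSE]
  if (!nrow(d)) stop("no records for province ", province)
  d$flight_order <- factor(d$flight_order)
  sizes <- table(d$flight_order)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("flight order(s) with < 2 observations excluded: ",
            paste(small, collapse = ", "), call. = FALSE)
    d <- droplevels(d[!(d$flight_order %in% small), , drop = FALSE])
  }
  k <- nlevels(d$flight_order)
  if (k < 2L) stop("tukey_by_province: need >= 2 flight orders with n >= 2")
  fit <- stats::aov(duration_dd ~ flight_order, data = d)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  dfres <- fit$df.residual
  lev <- levels(d$flight_order)
  n <- as.integer(table(d$flight_order))
  m <- tapply(d$duration_dd, d$flight_order, mean)
  pmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
    q <- abs(m[i] - m[j]) / se
    pmat[i, j] <- pmat[j, i] <- stats::ptukey(q, k, dfres, lower.tail = FALSE)
  }
  sig <- pmat < alpha
  letters <- compact_letters(sig)
  out <- data.frame(flight_order = lev, n = n,
                    mean_dd = as.numeric(m),
                    se_dd = sqrt(mse / n),
                    letters = letters)
  structure(out, pairwise = pmat, province = province, alpha = alpha,
            class = c("tukey_groups", "data.frame"))
}

# Greedy insert-absorb compact letter display from a logical significance
# matrix (TRUE = significantly different). Deterministic.
compact_letters <- function(sig) {
  k <- nrow(sig)
  lev <- rownames(sig)
  groups <- list(seq_len(k))               # start: everyone together
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (!isTRUE(sig[i, j])) next
    g <- 1L
    while (g <= length(groups)) {
      grp <- groups[[g]]
      if (i %in% grp && j %in% grp) {      # split the offending group
        groups[[g]] <- setdiff(grp, i)
        groups <- append(groups, list(setdiff(grp, j)), after = g)
        g <- g + 1L
      }
      g <- g + 1L
    }
    # absorb groups contained in another
    keep <- rep(TRUE, length(groups))
    for (a in seq_along(groups)) for (b in seq_along(groups))
      if (a != b && keep[a] && keep[b] &&
          all(groups[[a]] %in% groups[[b]])) keep[a] <- FALSE
    groups <- groups[keep]
  }
  ord <- order(vapply(groups, min, integer(1)))
  groups <- groups[ord]
  out <- character(k)
  for (g in seq_along(groups))
    out[groups[[g]]] <- paste0(out[groups[[g]]], letters[g])
  names(out) <- lev
  out
}

#' Jackknife standard error of a statistic
#'
#' Leave-one-out resampling estimate:
#' `SE = sqrt((n-1)/n * sum((theta_(i) - theta_bar)^2))`. For the mean this
#' reduces exactly to `sd(x)/sqrt(n)`.
#'
#' @param values Numeric vector, length >= 2.
#' @param statistic Function of a numeric vector (default `mean`).
#' @return The jackknife SE.
#' @examples
#' jackknife_se(c(1, 2, 3, 4, 5))    # = sd/sqrt(n) = 0.7071...
#' @export
jackknife_se <- function(values, statistic = mean) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L)
    stop(structure(class = c("ddphen_insufficient_data", "error", "condition"),
                   list(message = "jackknife_se: need at least 2 values",
                        call = sys.call())))
  theta <- vapply(seq_len(n), function(i) statistic(values[-i]), numeric(1))
  sqrt((n - 1) / n * sum((theta - mean(theta))^2))
}
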