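#' Repeated-measures ANOVA on window means
#'
#' Fully within-subject factorial ANOVA (2- or 3-way) on per-participant
#' condition means. Participants with missing cells are excluded and
#' reported. Per effect the univariate F is computed from orthonormal
#' contrast scores; the Greenhouse-Geisser epsilon corrects the p value for
#' sphericity violations on effects with more than one numerator df, and
#' generalized eta squared (effect SS over effect SS plus all
#' subject-linked error SS) is reported as the effect size.
#'
#' @param data data.frame with columns \code{subject}, \code{value}, and
#'   the factor columns named in \code{factors}.
#' @param factors character vector of within-subject factor names.
#' @return list: \code{effects} data.frame (effect, df1, df2, F, p,
#'   eps_GG, p_GG, ges), \code{excluded} subjects dropped for missing
#'   cells, \code{nSubjects}.
#' @export
windowFactorialAnova <- function(data, factors) {
  stopifnot(all(c("subject", "value", factors) %in% names(data)))
  for (f in factors) data[[f]] <- factor(data[[f]])
  # per-subject cell means
  cells <- interaction(data[factors], drop = FALSE, lex.order = TRUE)
  agg <- aggregate(value ~ subject + cells, data = transform(data, cells = cells),
                   FUN = mean)
  wide <- tapply(agg$value, list(agg$subject, agg$cells), identity)
  complete <- rowSums(is.na(wide)) == 0
  excluded <- rownames(wide)[!complete]
  if (length(excluded))
    warning("excluded for missing cells: ", paste(excluded, collapse = ", "))
  M <- wide[complete, , drop = FALSE]
  S <- nrow(M)
  if (S < 2) stop("need >= 2 complete subjects")
  lv <- lapply(factors, function(f) levels(data[[f]]))
  names(lv) <- factors
  nlev <- vapply(lv, length, 0L)
  # orthonormal contrast / mean vectors per factor, Kronecker over factors
  # in lex.order: the first factor varies slowest
  contr <- lapply(nlev, function(k) {
    cm <- contr.helmert(k)
    sweep(cm, 2, sqrt(colSums(cm^2)), "/")
  })
  unit <- lapply(nlev, function(k) matrix(1 / sqrt(k), k, 1))
  grand <- mean(M)
  subj_means <- rowMeans(M)
  ss_subject <- ncol(M) * sum((subj_means - grand)^2)
  effects <- unlist(lapply(seq_along(factors), function(ord)
    combn(factors, ord, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(effects, function(eff) {
    Cmat <- Reduce(kronecker, lapply(factors, function(f)
      if (f %in% eff) contr[[f]] else unit[[f]]))
    Y <- M %*% Cmat                       # S x df1 contrast scores
    df1 <- ncol(Y)
    mu <- colMeans(Y)
    ss_eff <- S * sum(mu^2)
    resid <- sweep(Y, 2, mu)
    ss_err <- sum(resid^2)
    df2 <- (S - 1) * df1
    Fv <- if (ss_eff == 0) 0 else if (ss_err == 0) Inf else
      (ss_eff / df1) / (ss_err / df2)
    if (df1 > 1) {
      Sig <- crossprod(resid) / (S - 1)
      eps <- sum(diag(Sig))^2 / (df1 * sum(Sig^2))
      eps <- min(max(eps, 1 / df1), 1)
    } else eps <- 1
    data.frame(effect = paste(eff, collapse = ":"), df1 = df1, df2 = df2,
               F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE),
               eps_GG = eps,
               p_GG = pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE),
               ss_effect = ss_eff, ss_error = ss_err)
  })
  tab <- do.call(rbind, rows)
  denom_err <- ss_subject + sum(tab$ss_error)
  tab$ges <- tab$ss_effect / (tab$ss_effect + denom_err)
  tab$ss_effect <- tab$ss_error <- NULL
  list(effects = tab, excluded = excluded, nSubjects = S)
}

#' Paired Wilcoxon signed-rank test with rank-biserial effect size
#'
#' Signed-rank test on paired samples; zero differences are dropped. The
#' exact null distribution is used up to n = 25 (ties permitting), the
#' normal approximation with tie correction beyond. The effect size is the
#' matched rank-biserial correlation (W+ - W-) / (W+ + W-).
#'
#' @param x,y paired numeric vectors.
#' @return list: \code{z}, \code{p} (two-sided), \code{r_rb}, \code{n}
#'   (non-zero pairs), \code{Wpos}, \code{Wneg}, \code{method}.
#' @export
pairedNonparametricTest <- function(x, y) {
  d <- x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("undefined test: all differences are zero")
  if (n < 5) stop("need >= 5 non-zero pairs")
  r <- rank(abs(d))
  Wpos <- sum(r[d > 0])
  Wneg <- sum(r[d < 0])
  ties <- table(r)
  mu <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- (Wpos - mu) / sqrt(sigma2)
  exact <- n <= 25 && !any(ties > 1)
  if (exact) {
    p <- if (Wpos > mu) {
      2 * psignrank(Wpos - 1, n, lower.tail = FALSE)
    } else if (Wpos < mu) {
      2 * psignrank(Wpos, n)
    } else 1
    p <- min(p, 1)
  } else {
    cc <- sign(Wpos - mu) * 0.5  # continuity correction
    p <- 2 * pnorm(abs((Wpos - mu - cc) / sqrt(sigma2)), lower.tail = FALSE)
  }
  list(z = z, p = p, r_rb = (Wpos - Wneg) / (Wpos + Wneg), n = n,
       Wpos = Wpos, Wneg = Wneg,
       method = if (exact) "exact" else "normal approximation")
}
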