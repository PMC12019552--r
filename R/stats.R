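#' Per-group mean with 95% confidence interval
#'
#' The figure-style summary: mean, n, SD and the t-based confidence
#' interval mean +/- t(1 - alpha/2, n - 1) * sd / sqrt(n) per group.
#'
#' @param values numeric vector of per-unit measurements.
#' @param group grouping factor/vector (one entry per value).
#' @param conf confidence level (default 0.95).
#' @return data.frame \code{group, n, mean, sd, ci_half, ci_lo, ci_hi};
#'   groups with n < 2 get NA intervals.
#' @export
groupSummary <- function(values, group, conf = 0.95) {
  stopifnot(length(values) == length(group), all(is.finite(values)))
  g <- factor(group)
  n <- as.integer(tapply(values, g, length))
  m <- as.numeric(tapply(values, g, mean))
  s <- as.numeric(tapply(values, g, stats::sd))
  half <- ifelse(n >= 2,
                 stats::qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n),
                 NA_real_)
  data.frame(group = levels(g), n = n, mean = m, sd = s, ci_half = half,
             ci_lo = m - half, ci_hi = m + half)
}

#' One-way ANOVA with Tukey HSD and a compact letter display
#'
#' Fits a one-way ANOVA, runs Tukey's all-pairs HSD, and labels the
#' groups with the insert-and-absorb compact letter display: two groups
#' share a letter exactly when their Tukey-adjusted p-value is at least
#' \code{alpha}. Zero-residual data (all groups internally constant)
#' degenerate gracefully: groups with identical means share a letter,
#' groups with different means do not; fully identical data get one
#' shared letter.
#'
#' @param values numeric response.
#' @param group grouping factor (>= 2 levels, each n >= 2).
#' @param alpha significance level of the letter display.
#' @return list: \code{letters} (named character vector, groups ordered
#'   by decreasing mean get earlier letters), \code{tukey} (data.frame
#'   of pairwise contrasts with adjusted p), \code{anova_p},
#'   \code{alpha}.
#' @export
anovaTukeyLetters <- function(values, group, alpha = 0.05) {
  g <- factor(group)
  stopifnot(nlevels(g) >= 2, all(table(g) >= 2), all(is.finite(values)))
  k <- nlevels(g)
  means <- tapply(values, g, mean)
  fit <- stats::aov(values ~ g)
  res_ms <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  pairs <- utils::combn(k, 2)
  if (res_ms <= .Machine$double.eps * max(abs(means), 1)^2) {
    ## zero within-group variance: differences are exact
    pdiff <- abs(means[pairs[1, ]] - means[pairs[2, ]]) >
      sqrt(.Machine$double.eps)
    tuk <- data.frame(group1 = levels(g)[pairs[1, ]],
                      group2 = levels(g)[pairs[2, ]],
                      diff = as.numeric(means[pairs[1, ]] -
                                          means[pairs[2, ]]),
                      p_adj = ifelse(pdiff, 0, 1))
    anova_p <- if (any(pdiff)) 0 else 1
  } else {
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    tuk <- data.frame(group1 = vapply(nm, `[`, "", 2),
                      group2 = vapply(nm, `[`, "", 1),
                      diff = -tk[, "diff"], p_adj = tk[, "p adj"])
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  }
  rownames(tuk) <- NULL
  sig <- matrix(FALSE, k, k, dimnames = list(levels(g), levels(g)))
  for (i in seq_len(nrow(tuk))) {
    s <- tuk$p_adj[i] < alpha
    sig[tuk$group1[i], tuk$group2[i]] <- s
    sig[tuk$group2[i], tuk$group1[i]] <- s
  }
  ## letters assigned in decreasing-mean order (convention of the plots)
  ord <- order(-means)
  letters_ord <- compactLetters(sig[ord, ord, drop = FALSE])
  letters_out <- letters_ord[match(levels(g), levels(g)[ord])]
  names(letters_out) <- levels(g)
  list(letters = letters_out, tukey = tuk, anova_p = anova_p,
       alpha = alpha)
}

#' Compact letter display by insert-and-absorb
#'
#' Given a symmetric logical matrix marking significantly different
#' pairs, produces letters such that two groups share a letter iff they
#' are NOT significantly different. Letter columns start as one column
#' holding every group; each significant pair splits every column
#' containing both; columns that became subsets of others are absorbed.
#'
#' @param sig k x k symmetric logical matrix (TRUE = significantly
#'   different), with group names as dimnames.
#' @return named character vector of letter strings, one per group, in
#'   the input order.
#' @export
compactLetters <- function(sig) {
  k <- nrow(sig)
  stopifnot(ncol(sig) == k, isTRUE(all(sig == t(sig))),
            !any(diag(sig)))
  cols <- list(seq_len(k))
  pr <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  for (e in seq_len(nrow(pr))) {
    i <- pr[e, 1]; j <- pr[e, 2]
    nxt <- list()
    for (cc in cols) {
      if (i %in% cc && j %in% cc)
        nxt <- c(nxt, list(setdiff(cc, i), setdiff(cc, j)))
      else nxt <- c(nxt, list(cc))
    }
    nxt <- nxt[lengths(nxt) > 0]
    ## absorb columns that are subsets of another column
    keep <- rep(TRUE, length(nxt))
    for (a in seq_along(nxt)) for (b in seq_along(nxt)) {
      if (a != b && keep[a] && keep[b] &&
          all(nxt[[a]] %in% nxt[[b]]) &&
          !(all(nxt[[b]] %in% nxt[[a]]) && a < b))
        keep[a] <- FALSE
    }
    cols <- nxt[keep]
  }
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  alphabet <- c(letters, as.vector(outer(letters, letters, paste0)))
  out <- vapply(seq_len(k), function(gi) {
    paste0(alphabet[which(vapply(cols, function(cc) gi %in% cc,
                                 logical(1)))], collapse = "")
  }, character(1))
  names(out) <- rownames(sig)
  out
}

#' Two-sample t-test (Student or Welch)
#'
#' @param a,b numeric samples (each n >= 2).
#' @param kind "student" (pooled variance, the default reported in the
#'   figure captions) or "welch".
#' @return list \code{statistic, df, p.value, mean_a, mean_b, kind}.
#' @export
twoSampleTest <- function(a, b, kind = c("student", "welch")) {
  kind <- match.arg(kind)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
    ## degenerate: identical within-group values
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (eq) 0 else Inf,
                df = length(a) + length(b) - 2,
                p.value = if (eq) 1 else 0,
                mean_a = mean(a), mean_b = mean(b), kind = kind))
  }
  ht <- stats::t.test(a, b, var.equal = (kind == "student"))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, mean_a = mean(a), mean_b = mean(b),
       kind = kind)
}
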