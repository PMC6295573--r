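#' Rank transform with mean ties
#'
#' Replaces pooled values by their ranks 1..n, assigning tied values the
#' mean of the ranks they occupy. Applied before the two-sample t-tests
#' because network properties depart from normality; the transform makes
#' the tests invariant to any monotone rescaling of the raw values.
#'
#' @param values numeric vector (>= 2 finite values).
#' @return numeric vector of ranks; sums to n(n+1)/2.
#' @export
rank_transform <- function(values) {
  stopifnot(sum(is.finite(values)) >= 2L)
  rank(values, ties.method = "average")
}

#' Normality check (Kolmogorov-Smirnov)
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the data. Because the parameters are estimated, the
#' p-value is approximate (the Lilliefors situation); it is used only to
#' report why the rank transform is applied, never as a gate.
#'
#' @param values numeric vector (>= 5 values).
#' @return list with `statistic`, `p.value`, and
#'   `estimated_params = TRUE` flagging the approximation.
#' @export
ks_normality <- function(values) {
  stopifnot(length(values) >= 5L)
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       estimated_params = TRUE)
}

#' Levene's test for equality of variances
#'
#' One-way ANOVA on absolute deviations from the group means (the
#' classical mean-centered form). Used to gate the choice between the
#' pooled-variance and Welch t statistics.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return list with `statistic` (F) and `p.value`.
#' @export
levene_test <- function(a, b) {
  za <- abs(a - mean(a))
  zb <- abs(b - mean(b))
  na <- length(za)
  nb <- length(zb)
  mza <- mean(za)
  mzb <- mean(zb)
  mz <- mean(c(za, zb))
  df2 <- na + nb - 2L
  ssb <- na * (mza - mz)^2 + nb * (mzb - mz)^2
  ssw <- sum((za - mza)^2) + sum((zb - mzb)^2)
  if (ssw == 0) {
    f <- if (ssb == 0) 0 else Inf
  } else {
    f <- (ssb / 1) / (ssw / df2)
  }
  list(statistic = f, p.value = stats::pf(f, 1, df2, lower.tail = FALSE))
}

#' Independent two-sample t-test with Levene gate
#'
#' Computes the t statistic for group A minus group B. Levene's test at
#' 0.05 selects between the pooled-variance t and the unequal-variance
#' (Welch) t with Welch-Satterthwaite degrees of freedom ("adjusted
#' p-value"). One-tailed mode with `direction = "observed"` takes the
#' tail from the sign of the observed mean difference — the replication
#' convention, which is anti-conservative and flagged as such; two-tailed
#' is the recommended default for new data.
#'
#' @param a,b numeric vectors (>= 2 values per group).
#' @param tails `"two"` or `"one"`.
#' @param direction for one-tailed tests: `"observed"` (tail follows the
#'   observed difference) or `"greater"` / `"less"` (a priori: A > B or
#'   A < B).
#' @param levene_alpha significance level of the variance gate.
#' @return list with `t`, `df`, `p`, `welch` (logical) and
#'   `levene_p`.
#' @export
two_sample_test <- function(a, b, tails = c("two", "one"),
                            direction = c("observed", "greater", "less"),
                            levene_alpha = 0.05) {
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  na <- length(a)
  nb <- length(b)
  stopifnot(na >= 2L, nb >= 2L)
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0 && mean(a) != mean(b)) {
    stop("degenerate variance in both groups with unequal means")
  }
  lev <- levene_test(a, b)
  welch <- is.finite(lev$p.value) && lev$p.value < levene_alpha
  diff <- mean(a) - mean(b)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  }
  t <- if (se2 == 0) 0 else diff / sqrt(se2)
  p <- switch(tails,
    two = 2 * stats::pt(-abs(t), df),
    one = switch(direction,
      observed = stats::pt(-abs(t), df),
      greater  = stats::pt(t, df, lower.tail = FALSE),
      less     = stats::pt(t, df)))
  list(t = t, df = df, p = p, welch = welch, levene_p = lev$p.value)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false-discovery-rate control across a family of p-values.
#' Rejections are all p at or below the largest p(k) with
#' p(k) <= k * alpha / m, equivalently q <= alpha for the monotone
#' adjusted values. Benjamini-Yekutieli is offered for dependent tests.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param alpha target FDR level.
#' @param method `"BH"` (default) or `"BY"`.
#' @return list with `q` (adjusted values) and `reject` (logical).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  q <- stats::p.adjust(pvalues, method = method)
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Classify an edge change between groups
#'
#' Four-way classification of a significant edge given the two group-mean
#' correlations. When the means share a sign, the edge is a decrease (in
#' that sign) if the AD magnitude is smaller than the NC magnitude, else
#' an increase. When the sign flips, a shrinking magnitude is a decrease
#' labeled by the NC sign, and a growing magnitude an increase labeled by
#' the AD sign — attenuation and enhancement are judged by movement of
#' the correlation toward or away from zero.
#'
#' @param mean_nc,mean_ad group-mean correlations in `[-1, 1]` (vectorized).
#' @return character vector: `"decrease-positive"`, `"decrease-negative"`,
#'   `"increase-positive"` or `"increase-negative"`.
#' @export
classify_edge_change <- function(mean_nc, mean_ad) {
  stopifnot(length(mean_nc) == length(mean_ad),
            all(abs(mean_nc) <= 1), all(abs(mean_ad) <= 1))
  mapply(function(nc, ad) {
    decreasing <- abs(ad) < abs(nc)
    sign_ref <- if (decreasing) nc else ad
    paste0(if (decreasing) "decrease" else "increase",
           if (sign_ref >= 0) "-positive" else "-negative")
  }, mean_nc, mean_ad, USE.NAMES = FALSE)
}

#' Outlier exclusion
#'
#' Default rule: Tukey IQR fences per group — values outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are dropped (quartiles by R's default
#' type-7 quantile). Alternatives: `"off"` (keep everything) and
#' `"zscore"` (drop |z| > 3).
#'
#' @param values numeric vector (>= 4 values for the IQR rule).
#' @param rule `"iqr"`, `"off"` or `"zscore"`.
#' @return list with `values` (retained), `excluded` (indices into the
#'   input) and `rule`.
#' @export
exclude_outliers <- function(values, rule = c("iqr", "off", "zscore")) {
  rule <- match.arg(rule)
  excluded <- integer(0)
  if (rule == "iqr") {
    stopifnot(length(values) >= 4L)
    q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    excluded <- which(values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr)
  } else if (rule == "zscore") {
    sdv <- stats::sd(values)
    if (is.finite(sdv) && sdv > 0) {
      excluded <- which(abs(values - mean(values)) / sdv > 3)
    }
  }
  kept <- if (length(excluded)) values[-excluded] else values
  list(values = kept, excluded = excluded, rule = rule)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mean-tied ranks; used to relate cognitive
#' scores (MMSE) to graph properties.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`, or `NA` with a warning for constant
#'   input.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rx <- rank_transform(x)
  ry <- rank_transform(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    ((length(x) - 1) * stats::sd(rx) * stats::sd(ry))
}

#' Edge-wise group comparison
#'
#' For each of the 2278 unique edges: excludes outliers per group, rank
#' transforms the pooled values, applies the Levene-gated independent
#' t-test, corrects across all edges with BH-FDR and classifies the
#' significant edges by their raw group-mean correlations.
#'
#' @param networks_nc,networks_ad lists of `conn_matrix` objects (>= 2
#'   subjects per group) sharing one atlas/region order.
#' @param alpha significance level after FDR.
#' @param tails,direction passed to [two_sample_test()]. The default is
#'   the a-priori two-tailed test; `tails = "one"` with
#'   `direction = "observed"` is the (anti-conservative) replication
#'   convention.
#' @param outlier_rule passed to [exclude_outliers()].
#' @param fdr_method passed to [bh_fdr()].
#' @return data.frame of class `edge_comparison`, one row per edge:
#'   `edge`, `region_a`, `region_b`, `mean_nc`, `mean_ad`, `n_nc`, `n_ad`
#'   (retained after exclusion), `t`, `df`, `p`, `q`, `significant`,
#'   `change_class` (`"none"` for non-significant edges).
#' @export
edgewise_comparison <- function(networks_nc, networks_ad, alpha = 0.05,
                                tails = "two", direction = "observed",
                                outlier_rule = "iqr", fdr_method = "BH") {
  stopifnot(length(networks_nc) >= 2L, length(networks_ad) >= 2L)
  regions <- networks_nc[[1L]]$regions
  for (net in c(networks_nc, networks_ad)) {
    if (!identical(net$regions, regions)) {
      stop("all networks must share the same region order")
    }
  }
  idx <- edge_index(regions)
  ij <- cbind(idx$i, idx$j)
  enc <- vapply(networks_nc, function(net) net$r[ij], numeric(nrow(idx)))
  ead <- vapply(networks_ad, function(net) net$r[ij], numeric(nrow(idx)))

  m <- nrow(idx)
  if (outlier_rule == "off" && (tails == "two" || direction == "observed")) {
    # vectorized fast path (no exclusion -> equal group sizes everywhere);
    # agreement with the per-edge route is asserted in the test suite
    na <- ncol(enc)
    nb <- ncol(ead)
    R <- t(apply(cbind(enc, ead), 1L, rank, ties.method = "average"))
    ra <- R[, seq_len(na), drop = FALSE]
    rb <- R[, na + seq_len(nb), drop = FALSE]
    ma <- rowMeans(ra)
    mb <- rowMeans(rb)
    va <- rowSums((ra - ma)^2) / (na - 1)
    vb <- rowSums((rb - mb)^2) / (nb - 1)
    # Levene gate (mean-centered) vectorized
    za <- abs(ra - ma)
    zb <- abs(rb - mb)
    mza <- rowMeans(za)
    mzb <- rowMeans(zb)
    mz <- (na * mza + nb * mzb) / (na + nb)
    ssb <- na * (mza - mz)^2 + nb * (mzb - mz)^2
    ssw <- rowSums((za - mza)^2) + rowSums((zb - mzb)^2)
    fstat <- ifelse(ssw == 0, ifelse(ssb == 0, 0, Inf),
                    ssb / (ssw / (na + nb - 2L)))
    lev_p <- stats::pf(fstat, 1, na + nb - 2L, lower.tail = FALSE)
    welch <- is.finite(lev_p) & lev_p < 0.05
    se2_w <- va / na + vb / nb
    df_w <- se2_w^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2L)
    se2_p <- sp2 * (1 / na + 1 / nb)
    se2 <- ifelse(welch, se2_w, se2_p)
    df <- ifelse(welch, df_w, na + nb - 2L)
    t_stat <- ifelse(se2 == 0, 0, (ma - mb) / sqrt(se2))
    p <- if (tails == "two") 2 * stats::pt(-abs(t_stat), df)
         else stats::pt(-abs(t_stat), df)
    mean_nc <- rowMeans(enc)
    mean_ad <- rowMeans(ead)
    n_nc <- rep(na, m)
    n_ad <- rep(nb, m)
  } else {
    t_stat <- df <- p <- mean_nc <- mean_ad <- numeric(m)
    n_nc <- n_ad <- integer(m)
    for (e in seq_len(m)) {
      a <- exclude_outliers(enc[e, ], outlier_rule)$values
      b <- exclude_outliers(ead[e, ], outlier_rule)$values
      mean_nc[e] <- mean(a)
      mean_ad[e] <- mean(b)
      n_nc[e] <- length(a)
      n_ad[e] <- length(b)
      pooled <- rank_transform(c(a, b))
      ra <- pooled[seq_along(a)]
      rb <- pooled[-seq_along(a)]
      ts <- two_sample_test(ra, rb, tails = tails, direction = direction)
      t_stat[e] <- ts$t
      df[e] <- ts$df
      p[e] <- ts$p
    }
  }
  fdr <- bh_fdr(p, alpha = alpha, method = fdr_method)
  cls <- rep("none", m)
  if (any(fdr$reject)) {
    cls[fdr$reject] <- classify_edge_change(mean_nc[fdr$reject],
                                            mean_ad[fdr$reject])
  }
  out <- data.frame(edge = idx$edge, region_a = idx$region_a,
                    region_b = idx$region_b, mean_nc = mean_nc,
                    mean_ad = mean_ad, n_nc = n_nc, n_ad = n_ad,
                    t = t_stat, df = df, p = p, q = fdr$q,
                    significant = fdr$reject, change_class = cls,
                    stringsAsFactors = FALSE)
  class(out) <- c("edge_comparison", class(out))
  out
}

#' Group-consensus hubs
#'
#' A region is a group hub when at least the consensus fraction of the
#' group's subjects have it as an individual hub (inclusive threshold:
#' the published tables retain regions at exactly 30% of 20 subjects).
#'
#' @param hub_sets list of per-subject hub region vectors.
#' @param regions character vector of all region identifiers.
#' @param threshold consensus fraction in `[0, 1]` (default 0.30).
#' @param nbc_matrix optional subjects x regions matrix of normalized
#'   betweenness to report the group-average nBC per region.
#' @param bc_matrix optional subjects x regions matrix of raw betweenness
#'   to report the group-average BC per region.
#' @return data.frame, one row per region: `region`, `fraction`,
#'   `is_hub`, and `avg_nbc` / `avg_bc` when the matrices are supplied.
#' @export
consensus_hubs <- function(hub_sets, regions, threshold = 0.30,
                           nbc_matrix = NULL, bc_matrix = NULL) {
  stopifnot(length(hub_sets) >= 1L, threshold >= 0, threshold <= 1)
  member <- vapply(hub_sets, function(h) regions %in% h,
                   logical(length(regions)))
  fraction <- rowMeans(member)
  out <- data.frame(region = regions, fraction = fraction,
                    is_hub = fraction >= threshold,
                    stringsAsFactors = FALSE)
  if (!is.null(nbc_matrix)) out$avg_nbc <- colMeans(nbc_matrix)
  if (!is.null(bc_matrix)) out$avg_bc <- colMeans(bc_matrix)
  out
}

#' MMSE-plus-network screening rule
#'
#' Combines the cognitive score with network properties to flag likely
#' patients. Any subject with MMSE below the zone lower bound is called
#' AD outright. Inside the high-MMSE zone (default 28-30), a subject is
#' flagged when global efficiency or mean local efficiency fall below, or
#' mean betweenness rises above, their decision thresholds. Thresholds
#' default to the midpoint of the two group means computed from a
#' labelled reference (training) set. This thresholding scheme is a
#' documented stand-in for an unspecified classifier, not a clinical
#' claim.
#'
#' @param metrics data.frame with columns `subject`, `mmse`, `e_global`,
#'   `m_e_local`, `m_bc`, and (if `thresholds` is NULL) `group` for
#'   threshold training.
#' @param zone MMSE zone bounds, default `c(28, 30)`.
#' @param thresholds optional named list/vector with `e_global`,
#'   `m_e_local`, `m_bc`; computed from group means when NULL.
#' @param vote `"majority"` (>= 2 of 3 properties), `"any"` (>= 1), or
#'   `"per-property"` (returns the three flags without a combined call).
#' @return data.frame of class `screening_result`: per subject `mmse`,
#'   `zone` (`"low"`/`"high"`), the three property flags, and `predicted`
#'   (`"AD"`/`"NC"`, NA under `"per-property"` voting inside the zone).
#'   The thresholds used are attached as attribute `"thresholds"`.
#' @export
mmse_screen <- function(metrics, zone = c(28, 30), thresholds = NULL,
                        vote = c("majority", "any", "per-property")) {
  vote <- match.arg(vote)
  stopifnot(zone[1] <= zone[2])
  need <- c("subject", "mmse", "e_global", "m_e_local", "m_bc")
  stopifnot(all(need %in% names(metrics)))
  if (anyNA(metrics$mmse)) stop("missing MMSE score(s)")
  if (is.null(thresholds)) {
    if (!"group" %in% names(metrics)) {
      stop("need a 'group' column to train thresholds, or pass thresholds=")
    }
    gm <- function(col) {
      tapply(metrics[[col]], metrics$group, mean)[c("NC", "AD")]
    }
    thresholds <- list(e_global = mean(gm("e_global")),
                       m_e_local = mean(gm("m_e_local")),
                       m_bc = mean(gm("m_bc")))
  }
  in_zone <- metrics$mmse >= zone[1] & metrics$mmse <= zone[2]
  flag_eg <- metrics$e_global < thresholds$e_global
  flag_el <- metrics$m_e_local < thresholds$m_e_local
  flag_bc <- metrics$m_bc > thresholds$m_bc
  votes <- flag_eg + flag_el + flag_bc
  predicted <- rep(NA_character_, nrow(metrics))
  predicted[!in_zone & metrics$mmse < zone[1]] <- "AD"
  if (vote != "per-property") {
    need_votes <- if (vote == "majority") 2L else 1L
    predicted[in_zone] <- ifelse(votes[in_zone] >= need_votes, "AD", "NC")
  }
  # MMSE above the zone cannot occur for a 30-point scale with zone top 30,
  # but treat it like the high zone if a custom zone is used
  above <- metrics$mmse > zone[2]
  if (any(above) && vote != "per-property") {
    need_votes <- if (vote == "majority") 2L else 1L
    predicted[above] <- ifelse(votes[above] >= need_votes, "AD", "NC")
  }
  out <- data.frame(subject = metrics$subject, mmse = metrics$mmse,
                    zone = ifelse(metrics$mmse < zone[1], "low", "high"),
                    flag_e_global = flag_eg, flag_m_e_local = flag_el,
                    flag_m_bc = flag_bc, predicted = predicted,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  attr(out, "vote") <- vote
  class(out) <- c("screening_result", class(out))
  out
}
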