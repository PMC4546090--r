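# Partially methylated domain (PMD) segmentation and classification.
#
# Segmentation uses a two-state hidden Markov model on window-level
# methylation: a PMD state with lower-mean Gaussian emissions and a
# background state with higher-mean emissions. Emission parameters are
# fit by EM from the pooled level histogram; transitions are fit by
# Baum-Welch with a sticky Dirichlet prior (domains are megabase-scale,
# so state flips are rare); the state path is decoded by Viterbi.

# --- two-state Gaussian HMM internals ---------------------------------

# EM fit of a 2-component Gaussian mixture (emission init).
fit_gaussian_mixture2 <- function(x, max_iter = 200L, tol = 1e-8) {
  q <- stats::quantile(x, c(0.15, 0.85), names = FALSE)
  mu <- q
  sd_ <- rep(max(stats::sd(x) / 2, 1e-3), 2L)
  pi_ <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pi_[1] * stats::dnorm(x, mu[1], sd_[1])
    d2 <- pi_[2] * stats::dnorm(x, mu[2], sd_[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    pi_ <- c(mean(r), 1 - mean(r))
    mu <- c(sum(r * x) / sum(r), sum((1 - r) * x) / sum(1 - r))
    sd_ <- sqrt(c(sum(r * (x - mu[1])^2) / sum(r),
                  sum((1 - r) * (x - mu[2])^2) / sum(1 - r)))
    sd_ <- pmax(sd_, 1e-3)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)  # state 1 = lower mean (PMD), state 2 = background
  list(mu = mu[ord], sd = sd_[ord], weight = pi_[ord])
}

# Scaled forward-backward for one observation sequence.
hmm_forward_backward <- function(emis, trans, init) {
  n <- nrow(emis)
  alpha <- matrix(0, n, 2L)
  beta <- matrix(0, n, 2L)
  scale <- numeric(n)
  a <- init * emis[1L, ]
  scale[1L] <- sum(a)
  alpha[1L, ] <- a / scale[1L]
  for (t in seq_len(n)[-1L]) {
    a <- (alpha[t - 1L, ] %*% trans) * emis[t, ]
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  beta[n, ] <- 1
  for (t in rev(seq_len(n - 1L))) {
    beta[t, ] <- (trans %*% (emis[t + 1L, ] * beta[t + 1L, ])) / scale[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(alpha = alpha, beta = beta, gamma = gamma, scale = scale,
       loglik = sum(log(scale)))
}

# Baum-Welch over a list of sequences; sticky Dirichlet prior on the
# transition diagonal.
fit_hmm2 <- function(seqs, mu, sd_, stay = 0.99, sticky_weight = 10,
                     max_iter = 50L, tol = 1e-6) {
  trans <- matrix(c(stay, 1 - stay, 1 - stay, stay), 2L, byrow = TRUE)
  init <- c(0.5, 0.5)
  prior <- sticky_weight * trans
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    num <- prior
    init_num <- c(1e-3, 1e-3)
    mu_num <- c(0, 0); mu_den <- c(0, 0); var_num <- c(0, 0)
    ll <- 0
    for (x in seqs) {
      emis <- cbind(stats::dnorm(x, mu[1], sd_[1]),
                    stats::dnorm(x, mu[2], sd_[2]))
      emis <- pmax(emis, 1e-300)
      fb <- hmm_forward_backward(emis, trans, init)
      ll <- ll + fb$loglik
      n <- length(x)
      if (n > 1L) {
        for (t in seq_len(n - 1L)) {
          xi <- trans * outer(fb$alpha[t, ],
                              emis[t + 1L, ] * fb$beta[t + 1L, ]) /
            fb$scale[t + 1L]
          num <- num + xi
        }
      }
      init_num <- init_num + fb$gamma[1L, ]
      mu_num <- mu_num + colSums(fb$gamma * x)
      mu_den <- mu_den + colSums(fb$gamma)
      var_num <- var_num + colSums(fb$gamma * (cbind(x - mu[1], x - mu[2]))^2)
    }
    trans <- num / rowSums(num)
    init <- init_num / sum(init_num)
    mu <- mu_num / mu_den
    sd_ <- pmax(sqrt(var_num / mu_den), 1e-3)
    if (mu[1] > mu[2]) {  # keep state 1 = lower mean
      mu <- rev(mu); sd_ <- rev(sd_); init <- rev(init)
      trans <- trans[2:1, 2:1]
    }
    if (is.finite(ll) && abs(ll - ll_old) < tol * abs(ll_old + 1)) break
    ll_old <- ll
  }
  list(mu = mu, sd = sd_, trans = trans, init = init, loglik = ll)
}

hmm_viterbi2 <- function(x, model) {
  n <- length(x)
  log_emis <- cbind(stats::dnorm(x, model$mu[1], model$sd[1], log = TRUE),
                    stats::dnorm(x, model$mu[2], model$sd[2], log = TRUE))
  lt <- log(model$trans)
  v <- matrix(-Inf, n, 2L)
  ptr <- matrix(1L, n, 2L)
  v[1L, ] <- log(model$init) + log_emis[1L, ]
  for (t in seq_len(n)[-1L]) {
    for (s in 1:2) {
      cand <- v[t - 1L, ] + lt[, s]
      ptr[t, s] <- which.max(cand)
      v[t, s] <- cand[ptr[t, s]] + log_emis[t, s]
    }
  }
  path <- integer(n)
  path[n] <- which.max(v[n, ])
  for (t in rev(seq_len(n - 1L))) path[t] <- ptr[t + 1L, path[t + 1L]]
  path
}

# --- public operations ------------------------------------------------

#' Segment a methylome into partially methylated domains
#'
#' Fits the two-state HMM on the informative windows of a nonoverlapping
#' window track (typically 10-kb windows with at least 5 CGs), decodes
#' each chromosome by Viterbi, merges consecutive PMD-state windows into
#' segments, and drops segments shorter than `min_length`. A separate
#' `report_min_length` (default 500 kb) mirrors the convention of
#' displaying only large domains; both filtered sets are returned.
#'
#' If the two fitted emission means are closer than `min_separation` the
#' level distribution is effectively unimodal and no PMDs are called.
#'
#' @param track nonoverlapping window track from [window_levels()].
#' @param min_length minimum detected-segment length in bp (default
#'   1e5).
#' @param report_min_length display threshold in bp (default 5e5).
#' @param min_separation minimum difference between state means for any
#'   PMD call (default 0.1).
#' @return list with `segments` (chrom, start, end, mean_level,
#'   n_windows; >= `min_length`), `reported` (subset >=
#'   `report_min_length`), and the fitted `model`.
#' @export
segment_pmds <- function(track, min_length = 1e5, report_min_length = 5e5,
                         min_separation = 0.1) {
  informative <- track[!is.na(track$level), , drop = FALSE]
  if (nrow(informative) < 50L) {
    stop("fewer than 50 informative windows; cannot fit emission model")
  }
  mix <- fit_gaussian_mixture2(informative$level)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), mean_level = numeric(),
                      n_windows = integer())
  seqs <- split(informative, informative$chrom)
  model <- fit_hmm2(lapply(seqs, `[[`, "level"), mix$mu, mix$sd)
  if (diff(model$mu) < min_separation) {
    return(list(segments = empty, reported = empty, model = model))
  }
  seg_list <- lapply(seqs, function(sub) {
    path <- hmm_viterbi2(sub$level, model)
    runs <- rle(path)
    ends_idx <- cumsum(runs$lengths)
    starts_idx <- ends_idx - runs$lengths + 1L
    pmd_runs <- which(runs$values == 1L)
    if (!length(pmd_runs)) return(NULL)
    data.frame(
      chrom = sub$chrom[1L],
      start = sub$start[starts_idx[pmd_runs]],
      end = sub$end[ends_idx[pmd_runs]],
      mean_level = vapply(pmd_runs, function(i) {
        idx <- starts_idx[i]:ends_idx[i]
        sum(sub$level[idx] * sub$n_reads[idx]) / sum(sub$n_reads[idx])
      }, numeric(1)),
      n_windows = runs$lengths[pmd_runs]
    )
  })
  segments <- do.call(rbind, seg_list)
  if (is.null(segments)) segments <- empty
  segments <- segments[segments$end - segments$start >= min_length, ,
                       drop = FALSE]
  rownames(segments) <- NULL
  reported <- segments[segments$end - segments$start >= report_min_length, ,
                       drop = FALSE]
  list(segments = segments, reported = reported, model = model)
}

#' Classify windows by PMD overlap
#'
#' A window overlapping any PMD by at least 1 bp (half-open intervals:
#' merely touching does not overlap) is labeled `"PMD"`, the rest
#' `"non-PMD"`. PMD calls are conventionally taken from the P0.5
#' prospermatogonium methylome and the labels carried to other stages.
#'
#' @param windows window track or interval data.frame.
#' @param pmds PMD segments (chrom, start, end).
#' @return character vector of labels, one per window.
#' @export
classify_windows_pmd <- function(windows, pmds) {
  labels <- rep("non-PMD", nrow(windows))
  if (nrow(pmds)) {
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(windows$chrom,
                             IRanges::IRanges(windows$start + 1L,
                                              windows$end)),
      GenomicRanges::GRanges(pmds$chrom,
                             IRanges::IRanges(pmds$start + 1L, pmds$end))
    )
    labels[unique(S4Vectors::queryHits(hits))] <- "PMD"
  }
  labels
}

#' Strand-aware promoter intervals
#'
#' The promoter spans `upstream` bp upstream to `downstream` bp
#' downstream of the TSS: `[tss - upstream, tss + downstream)` on the
#' plus strand, reflected on the minus strand, clipped at 0.
#'
#' @param genes gene models with `tss` and `strand`.
#' @param upstream,downstream extents in bp (defaults 2000 and 500, the
#'   promoter rule used for PMD gene classification).
#' @return data.frame `chrom`, `start`, `end`, `id`.
#' @export
promoter_intervals <- function(genes, upstream = 2000L, downstream = 500L) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  data.frame(chrom = genes$chrom, start = pmax(0L, as.integer(start)),
             end = as.integer(end), id = genes$id)
}

#' Label genes by promoter-PMD overlap
#'
#' A gene whose promoter (2000 bp upstream to 500 bp downstream of the
#' TSS, strand-aware) overlaps any PMD by at least 1 bp is a PMD gene.
#'
#' @param genes gene models.
#' @param pmds PMD segments.
#' @return character vector `"PMD"`/`"non-PMD"` aligned to `genes` rows.
#' @export
assign_pmd_genes <- function(genes, pmds) {
  classify_windows_pmd(promoter_intervals(genes), pmds)
}

#' Expression summary of PMD vs non-PMD genes
#'
#' Transforms FPKM to log2(FPKM + 1) and summarizes the two gene groups.
#'
#' @param labels `"PMD"`/`"non-PMD"` per gene (as from
#'   [assign_pmd_genes()]).
#' @param fpkm numeric FPKM vector aligned to `labels`.
#' @return list with per-group transformed values (`pmd`, `non_pmd`) and
#'   their medians (`median_pmd`, `median_non_pmd`).
#' @export
pmd_expression_summary <- function(labels, fpkm) {
  stopifnot(length(labels) == length(fpkm))
  lv <- log2(fpkm + 1)
  pmd <- lv[labels == "PMD"]
  non <- lv[labels == "non-PMD"]
  list(pmd = pmd, non_pmd = non,
       median_pmd = stats::median(pmd), median_non_pmd = stats::median(non))
}
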