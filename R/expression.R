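#' log2(x + pseudocount) transform
#' @param m Nonnegative numeric matrix (FPKM).
#' @param pseudocount Added before the log (default 1).
#' @return Transformed matrix.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  if (any(m < 0)) stop("expression values must be nonnegative")
  log2(m + pseudocount)
}

#' Select differentially expressed genes per condition
#'
#' For each stress condition, per-timepoint log2 fold changes are
#' `log2((FPKM_stress + 1) / (FPKM_control + 1))` with replicates averaged
#' within condition x timepoint. The p-value is a two-sided paired t-test
#' across matched stress/control observations (condition x timepoint x
#' replicate) when at least three pairs exist, otherwise a Welch t-test
#' across replicates on the log scale. A gene is a DEG when `p <= alpha` and
#' the largest absolute per-timepoint log2 fold change reaches
#' `min_abs_log2fc`; genes with too few observations are flagged
#' `untestable`.
#'
#' @param fpkm Numeric matrix, genes x samples.
#' @param samples data.frame with columns `sample`, `condition`,
#'   `timepoint`, `replicate`; the control condition is named `control`.
#' @param alpha p-value threshold (default 0.05).
#' @param min_abs_log2fc Minimum absolute log2 fold change (default 1).
#' @return list per stress condition: data.frame with `gene`, `p_value`,
#'   `max_abs_log2fc`, `deg`, `untestable`, plus a `log2fc` matrix
#'   (genes x timepoints).
#' @export
select_degs <- function(fpkm, samples, alpha = 0.05, min_abs_log2fc = 1) {
  stopifnot(identical(colnames(fpkm), samples$sample))
  conds <- setdiff(unique(samples$condition), "control")
  if (!any(samples$condition == "control")) {
    stop("no control samples present")
  }
  out <- list()
  for (cond in conds) {
    s_idx <- which(samples$condition == cond)
    tps <- sort(unique(samples$timepoint[s_idx]))
    log2fc <- matrix(NA_real_, nrow(fpkm), length(tps),
                     dimnames = list(rownames(fpkm), as.character(tps)))
    pair_s <- pair_c <- list()
    for (tp in tps) {
      si <- which(samples$condition == cond & samples$timepoint == tp)
      ci <- which(samples$condition == "control" & samples$timepoint == tp)
      if (!length(ci)) ci <- which(samples$condition == "control")
      ms <- rowMeans(fpkm[, si, drop = FALSE])
      mc <- rowMeans(fpkm[, ci, drop = FALSE])
      log2fc[, as.character(tp)] <- log2((ms + 1) / (mc + 1))
      for (r in sort(unique(samples$replicate[si]))) {
        sri <- si[samples$replicate[si] == r]
        cri <- ci[samples$replicate[ci] == r]
        if (length(sri) == 1 && length(cri) == 1) {
          pair_s[[length(pair_s) + 1]] <- log2(fpkm[, sri] + 1)
          pair_c[[length(pair_c) + 1]] <- log2(fpkm[, cri] + 1)
        }
      }
    }
    n_pairs <- length(pair_s)
    ps <- rep(NA_real_, nrow(fpkm))
    untestable <- rep(FALSE, nrow(fpkm))
    if (n_pairs >= 3) {
      ms <- do.call(cbind, pair_s)
      mc <- do.call(cbind, pair_c)
      for (g in seq_len(nrow(fpkm))) {
        d <- ms[g, ] - mc[g, ]
        if (sd(d) == 0) {
          ps[g] <- if (all(d == 0)) 1 else 0
        } else {
          ps[g] <- t.test(ms[g, ], mc[g, ], paired = TRUE)$p.value
        }
      }
    } else {
      si <- which(samples$condition == cond)
      ci <- which(samples$condition == "control")
      if (length(si) >= 2 && length(ci) >= 2) {
        for (g in seq_len(nrow(fpkm))) {
          xs <- log2(fpkm[g, si] + 1)
          xc <- log2(fpkm[g, ci] + 1)
          if (sd(xs) == 0 && sd(xc) == 0) {
            ps[g] <- if (mean(xs) == mean(xc)) 1 else 0
          } else {
            ps[g] <- t.test(xs, xc)$p.value
          }
        }
      } else {
        untestable[] <- TRUE
      }
    }
    max_fc <- apply(abs(log2fc), 1, max)
    out[[cond]] <- list(
      table = data.frame(
        gene = rownames(fpkm), p_value = ps, max_abs_log2fc = max_fc,
        deg = !untestable & !is.na(ps) & ps <= alpha &
          max_fc >= min_abs_log2fc,
        untestable = untestable, stringsAsFactors = FALSE),
      log2fc = log2fc)
  }
  out
}

#' Standardise matrix rows to mean 0, sd 1
#'
#' Zero-variance rows cannot be standardised and are dropped with a warning.
#'
#' @param m Numeric matrix.
#' @return Standardised matrix (possibly with fewer rows).
#' @export
standardize_rows <- function(m) {
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance row(s)")
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (m - rowMeans(m)) / sds
}

#' Choose the number of clusters by the k-means elbow
#'
#' Runs k-means (10 restarts, seeded) for each k in the range and picks the
#' elbow: the k with the largest second difference of the within-cluster sum
#' of squares. When no pronounced elbow exists (largest curvature below 30%
#' of the total WSS drop over the range, a margin that separates smooth
#' noise curves from genuinely clustered data) the smallest k is returned.
#'
#' @param m Numeric matrix (rows clustered).
#' @param k_range Candidate k values (default 2:10).
#' @param seed Integer seed.
#' @return Chosen k.
#' @export
choose_k <- function(m, k_range = 2:10, seed = 1) {
  stopifnot(nrow(m) >= max(k_range))
  ks <- sort(k_range)
  wss <- vapply(ks, function(k) {
    set.seed(seed + k)
    kmeans(m, centers = k, nstart = 10, iter.max = 100)$tot.withinss
  }, numeric(1))
  if (length(ks) < 3) return(ks[1])
  d2 <- wss[1:(length(ks) - 2)] - 2 * wss[2:(length(ks) - 1)] +
    wss[3:length(ks)]
  drop_total <- wss[1] - wss[length(ks)]
  if (drop_total <= 0 || max(d2) < 0.3 * drop_total) return(ks[1])
  ks[which.max(d2) + 1]
}

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means: memberships proportional to
#' `distance^(-2/(m-1))`, centers the membership^m-weighted means, iterated
#' from a seeded random membership initialisation until the objective
#' improves by less than `tol`.
#'
#' @param m Numeric matrix (rows are items).
#' @param k Number of clusters (>= 2).
#' @param fuzzifier Fuzzifier m > 1 (default 1.25, the usual soft-clustering
#'   choice for standardised expression profiles).
#' @param tol Convergence tolerance on the objective.
#' @param max_iter Iteration cap.
#' @param seed Integer seed.
#' @return list of class `aqp_fcm` with `membership` (rows x k,
#'   row-stochastic), `centers`, `objective` (trace) and `cluster` (hard
#'   assignment by maximal membership).
#' @export
fuzzy_cmeans <- function(m, k, fuzzifier = 1.25, tol = 1e-6, max_iter = 1000,
                         seed = 1) {
  stopifnot(k >= 2, fuzzifier > 1)
  n <- nrow(m)
  if (k > n) stop("more clusters than rows")
  set.seed(seed)
  U <- matrix(runif(n * k), n, k)
  U <- U / rowSums(U)
  obj_trace <- numeric()
  for (iter in seq_len(max_iter)) {
    W <- U^fuzzifier
    centers <- (t(W) %*% m) / colSums(W)
    d2 <- outer(rowSums(m^2), rep(1, k)) - 2 * m %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2[d2 < 1e-12] <- 1e-12
    obj <- sum(W * d2)
    obj_trace <- c(obj_trace, obj)
    if (iter > 1 && abs(obj_trace[iter - 1] - obj) < tol) break
    U <- d2^(-1 / (fuzzifier - 1))
    U <- U / rowSums(U)
  }
  rownames(U) <- rownames(m)
  structure(list(membership = U, centers = centers, objective = obj_trace,
                 fuzzifier = fuzzifier,
                 cluster = setNames(max.col(U), rownames(m))),
            class = "aqp_fcm")
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up FDR: `fdr_i = min_{j >= rank(i)} m p_(j) / j`, capped at 1;
#' stable under input order.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return FDR-adjusted values in input order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' GO term enrichment by the hypergeometric (Fisher) upper tail
#'
#' For each GO term annotating the background, the one-sided p-value is
#' `P(X >= k)` with `X ~ Hypergeom(N, n, K)` (`N` background genes, `n`
#' annotated in the background, `K` cluster size, `k` annotated in the
#' cluster); Benjamini-Hochberg correction is applied across the terms of
#' the cluster and terms at `fdr <= fdr_threshold` are flagged enriched.
#' Unannotated genes count toward the totals.
#'
#' @param cluster_genes Character vector, a subset of the background.
#' @param background_genes Character vector of all genes.
#' @param go_map Named list: gene id to character vector of GO ids.
#' @param fdr_threshold Enrichment cut-off (default 0.01).
#' @return data.frame with `term`, `k`, `K`, `n`, `N`, `p_value`, `fdr`,
#'   `enriched`, ordered by p-value.
#' @export
fisher_enrichment <- function(cluster_genes, background_genes, go_map,
                              fdr_threshold = 0.01) {
  if (!length(cluster_genes)) stop("empty cluster")
  stopifnot(all(cluster_genes %in% background_genes))
  N <- length(background_genes)
  K <- length(cluster_genes)
  ann <- go_map[intersect(names(go_map), background_genes)]
  terms <- sort(unique(unlist(ann)))
  if (!length(terms)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      fdr = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  }
  genes_by_term <- list()
  for (g in names(ann)) for (tm in ann[[g]]) {
    genes_by_term[[tm]] <- c(genes_by_term[[tm]], g)
  }
  k <- vapply(terms, function(tm)
    sum(cluster_genes %in% genes_by_term[[tm]]), integer(1))
  n <- vapply(terms, function(tm) length(genes_by_term[[tm]]), integer(1))
  p <- phyper(k - 1, n, N - n, K, lower.tail = FALSE)
  fdr <- benjamini_hochberg(p)
  out <- data.frame(term = terms, k = k, K = K, n = n, N = N, p_value = p,
                    fdr = fdr, enriched = fdr <= fdr_threshold,
                    stringsAsFactors = FALSE)
  out[order(out$p_value, out$term), ]
}
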