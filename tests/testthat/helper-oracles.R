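# Independent oracles used to validate the package's analytic machinery.
# Each is a deliberately naive implementation (plain recursion, exhaustive
# enumeration, fine-grid numerics) sharing no code with the package.

# --- global alignment: exhaustive recursion over all affine-gap alignments ---
# gap of length k costs open + (k - 1) * extend, as in align_global()
oracle_align_score <- function(a, b, submat, gap_open, gap_extend) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(ac) && j > length(bc)) return(0)
    best <- -Inf
    if (i <= length(ac) && j <= length(bc)) {
      best <- max(best, submat[ac[i], bc[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(ac)) {
      cost <- if (prev == "U") gap_extend else gap_open
      best <- max(best, -cost + rec(i + 1, j, "U"))
    }
    if (j <= length(bc)) {
      cost <- if (prev == "L") gap_extend else gap_open
      best <- max(best, -cost + rec(i, j + 1, "L"))
    }
    best
  }
  rec(1, 1, "M")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# --- AUPRC: fine-grid numeric integration of the interpolated curve ---
# achievable points recomputed from scratch; fp linear in tp between points
oracle_auprc_grid <- function(truth, score, n_grid = 20000) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  blocks <- unname(split(seq_along(score), factor(-score, levels = unique(-score))))
  tp <- c(0, cumsum(vapply(blocks, function(i) sum(truth[i]), numeric(1))))
  fp <- c(0, cumsum(vapply(blocks, function(i) sum(!truth[i]), numeric(1))))
  n_pos <- sum(truth)
  # integrate precision over each achievable segment on a fine grid, with
  # fp linear in tp within the segment (vertical drops carry no area)
  total <- 0
  for (i in seq_len(length(tp) - 1)) {
    dtp <- tp[i + 1] - tp[i]
    if (dtp == 0) next
    slope <- (fp[i + 1] - fp[i]) / dtp
    x <- seq(tp[i], tp[i + 1], length.out = n_grid + 1)[-1]
    prec <- x / (x + fp[i] + slope * (x - tp[i]))
    total <- total + sum(prec) * dtp / n_grid
  }
  total / n_pos
}

# --- AUROC: exhaustive positive x negative pair comparison ---
oracle_auroc_pairs <- function(truth, score) {
  pos <- score[truth]
  neg <- score[!truth]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# --- Clopper-Pearson: bisection on binomial tail sums ---
oracle_cp_interval <- function(k, n, level = 0.95) {
  alpha <- (1 - level) / 2
  tail_ge <- function(p) sum(dbinom(k:n, n, p))   # P(X >= k)
  tail_le <- function(p) sum(dbinom(0:k, n, p))   # P(X <= k)
  bisect <- function(f, target, lo, hi, increasing) {
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if ((f(mid) < target) == increasing) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else bisect(tail_ge, alpha, 0, 1, increasing = TRUE)
  upper <- if (k == n) 1 else bisect(tail_le, alpha, 0, 1, increasing = FALSE)
  c(lower, upper)
}

# --- Wilcoxon rank-sum: exact enumeration for tie-free samples ---
oracle_wilcoxon_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- combn(n + m, n)
  u_all <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]) - n * (n + 1) / 2)
  p <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  list(u = u_obs, p = p)
}

# --- Fisher exact: hypergeometric enumeration with fixed margins ---
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- pair selection: plain re-application of the five filters ---
oracle_select <- function(pairs, genes, domains, cutoff) {
  sig <- domains[domains$e_value <= cutoff, c("gene_id", "accession")]
  sig <- unique(sig)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    h <- genes[genes$gene_id == pairs$human_gene[i], ]
    y <- genes[genes$gene_id == pairs$yeast_gene[i], ]
    yd <- sig$accession[sig$gene_id == pairs$yeast_gene[i]]
    hd <- sig$accession[sig$gene_id == pairs$human_gene[i]]
    keep[i] <- !pairs$annotated_ortholog[i] &&
      isTRUE(h$is_disease_gene) && isTRUE(h$clone_available) &&
      isTRUE(y$is_essential) && isTRUE(y$ts_allele_available) &&
      all(yd %in% hd)
  }
  out <- pairs[keep, , drop = FALSE]
  out[order(out$human_gene, out$yeast_gene), , drop = FALSE]
}

# small random selection universe with attributes and domains
random_universe <- function(n_pairs = 12, seed = NULL) {
  gen <- function() {
    hum <- sprintf("H%02d", 1:6)
    yst <- sprintf("Y%02d", 1:5)
    genes <- rbind(
      data.frame(gene_id = hum, species = "human",
                 is_disease_gene = sample(c(TRUE, FALSE), 6, TRUE),
                 clone_available = sample(c(TRUE, FALSE), 6, TRUE),
                 is_essential = NA, ts_allele_available = NA),
      data.frame(gene_id = yst, species = "yeast",
                 is_disease_gene = NA, clone_available = NA,
                 is_essential = sample(c(TRUE, FALSE), 5, TRUE),
                 ts_allele_available = sample(c(TRUE, FALSE), 5, TRUE))
    )
    pool <- sprintf("PF%05d", 1:6)
    ids <- c(hum, yst)
    domains <- do.call(rbind, lapply(ids, function(g) {
      k <- sample(1:3, 1)
      data.frame(gene_id = g, accession = sample(pool, k),
                 e_value = 10^runif(k, -10, 0))
    }))
    pairs <- unique(data.frame(
      human_gene = sample(hum, n_pairs, TRUE),
      yeast_gene = sample(yst, n_pairs, TRUE)
    ))
    pairs$annotated_ortholog <- sample(c(TRUE, FALSE), nrow(pairs), TRUE,
                                       prob = c(0.3, 0.7))
    list(pairs = tibble::as_tibble(pairs), genes = tibble::as_tibble(genes),
         domains = tibble::as_tibble(domains))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# labelled random score table for curve statistics
random_score_table <- function(n, prevalence = 0.5, ties = FALSE) {
  s <- if (ties) sample(seq(0, 1, 0.1), n, replace = TRUE) else runif(n)
  tibble::tibble(
    disease_associated = seq_len(n) <= round(n * prevalence),
    s = s
  )
}

spec_s <- function() score_spec("s", "s", "higher_is_damaging", 0.5)

blosum62_20 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  e$BLOSUM62[aa, aa]
})
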