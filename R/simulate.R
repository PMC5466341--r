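#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with the study's
#' default conditions. Defaults are anchored to the benchmark panel:
#' 79% of disease variants and 25% of benign variants carry high latent
#' damage (the observed deleterious-call rates), the variant panel is
#' ~54% disease-associated (19 of 35), the assay uses 5-spot 10-fold
#' dilution series over the 24-38 degree temperature panel, and
#' complementing pairs have percent-identity distributions shifted upward
#' by 7 points over non-complementing pairs (mean 25, sd 10), which
#' reproduces the published operating point of a 30% PID cutoff capturing
#' ~60% of complementing and ~30% of non-complementing pairs.
#'
#' @param seed Integer seed; fully determines generator output.
#' @param n_yeast_genes,n_human_genes,n_pairs Universe sizes.
#' @param frac_essential,frac_ts_available Yeast gene attribute rates.
#' @param frac_disease,frac_clone Human gene attribute rates.
#' @param domain_pool_size,mean_domains_per_gene Domain model: accessions
#'   are drawn from a pool of this size, per-gene counts are
#'   1 + Poisson(mean - 1).
#' @param frac_covered Fraction of yeast genes whose significant domains
#'   are constructed to be covered by a human partner.
#' @param complementation_base_rate P(pair complements).
#' @param pid_mean_noncomp,pid_sd,pid_shift_complementing Class-conditional
#'   PID model (normal, truncated to \[1, 99\]); complementing pairs are
#'   shifted up by `pid_shift_complementing` points.
#' @param n_variants,frac_disease_variants Variant panel size and disease
#'   fraction.
#' @param frac_damaging_given_disease,frac_damaging_given_benign
#'   Probability that a disease (resp. benign) variant carries high latent
#'   damage.
#' @param assay_noise Probability that any single spot's visibility flips.
#' @param dilution_steps Spots per dilution series.
#' @param temperature_panel,permissive_temps Assay temperatures; the
#'   permissive ones show full growth for every plasmid.
#' @param gfp_baseline,wt_rescue Spots grown by the GFP control and
#'   additionally rescued by the wild-type plasmid at restrictive
#'   temperatures.
#' @param pph2_noise_sd,provean_noise_sd Gaussian noise of the simulated
#'   computational scores (logit and linear scale respectively).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_yeast_genes = 40, n_human_genes = 80, n_pairs = 200,
                       frac_essential = 0.3, frac_ts_available = 0.6,
                       frac_disease = 0.5, frac_clone = 0.8,
                       domain_pool_size = 30, mean_domains_per_gene = 2,
                       frac_covered = 0.5,
                       complementation_base_rate = 0.15,
                       pid_mean_noncomp = 25, pid_sd = 10,
                       pid_shift_complementing = 7,
                       n_variants = 200, frac_disease_variants = 19 / 35,
                       frac_damaging_given_disease = 0.79,
                       frac_damaging_given_benign = 0.25,
                       assay_noise = 0.02, dilution_steps = 5,
                       temperature_panel = c(24, 28, 30, 32, 33, 34, 35, 36, 38),
                       permissive_temps = c(24, 28),
                       gfp_baseline = 1, wt_rescue = 4,
                       pph2_noise_sd = 1, provean_noise_sd = 1.5) {
  cfg <- as.list(environment())
  for (p in c("frac_essential", "frac_ts_available", "frac_disease",
              "frac_clone", "frac_covered", "complementation_base_rate",
              "frac_disease_variants", "frac_damaging_given_disease",
              "frac_damaging_given_benign", "assay_noise")) {
    check_prob(cfg[[p]], p)
  }
  if (cfg$gfp_baseline + cfg$wt_rescue > cfg$dilution_steps) {
    abort("gfp_baseline + wt_rescue cannot exceed dilution_steps.")
  }
  if (!all(cfg$permissive_temps %in% cfg$temperature_panel)) {
    abort("permissive_temps must be a subset of temperature_panel.")
  }
  structure(cfg, class = "sim_config")
}

as_sim_config <- function(config) {
  if (inherits(config, "sim_config")) config else do.call(sim_config, config)
}

#' Simulate a gene/domain/pair universe with planted selection truth
#'
#' Generates human and yeast gene records, Pfam-style domain hits and
#' candidate homolog pairs with class-conditional percent identities, plus
#' a ground-truth table recording, per pair, every filter outcome and the
#' expected selection decision. The ground truth is emitted for testing
#' only and is never consumed by pipeline stages.
#'
#' @param config A [sim_config()].
#' @return A list with tibbles `genes`, `domains`, `pairs` and `truth`
#'   (per-pair filter flags and `should_pass`).
#' @export
simulate_gene_universe <- function(config = sim_config()) {
  config <- as_sim_config(config)
  if (config$n_yeast_genes < 1 || config$n_human_genes < 1 || config$n_pairs < 1) {
    abort("Universe sizes must be positive.")
  }
  if (config$frac_disease == 0 && config$frac_essential == 0) {
    abort("Degenerate config: no disease genes and no essential genes possible.")
  }
  withr::with_seed(config$seed, {
    hum <- sprintf("HSA%04d", seq_len(config$n_human_genes))
    yst <- sprintf("YST%04d", seq_len(config$n_yeast_genes))
    genes <- dplyr::bind_rows(
      tibble::tibble(
        gene_id = hum, species = "human",
        is_disease_gene = runif(length(hum)) < config$frac_disease,
        clone_available = runif(length(hum)) < config$frac_clone,
        is_essential = NA, ts_allele_available = NA
      ),
      tibble::tibble(
        gene_id = yst, species = "yeast",
        is_disease_gene = NA, clone_available = NA,
        is_essential = runif(length(yst)) < config$frac_essential,
        ts_allele_available = runif(length(yst)) < config$frac_ts_available
      )
    )

    pool <- sprintf("PF%05d", seq_len(config$domain_pool_size))
    draw_domains <- function(ids, from) {
      purrr::map(ids, function(g) {
        k <- 1 + rpois(1, max(config$mean_domains_per_gene - 1, 0))
        sample(from, min(k, length(from)))
      })
    }
    human_doms <- draw_domains(hum, pool)
    names(human_doms) <- hum

    # candidate pairs first, so covered yeast genes can copy a partner's set
    pair_idx <- tibble::tibble(
      human_gene = sample(hum, config$n_pairs, replace = TRUE),
      yeast_gene = sample(yst, config$n_pairs, replace = TRUE)
    ) |> dplyr::distinct()

    covered_yeast <- setNames(runif(length(yst)) < config$frac_covered, yst)
    yeast_doms <- purrr::map(yst, function(y) {
      partners <- pair_idx$human_gene[pair_idx$yeast_gene == y]
      if (covered_yeast[[y]] && length(partners) > 0) {
        src <- human_doms[[sample(partners, 1)]]
        sample(src, max(1, min(length(src), 1 + rpois(1, 0.5))))
      } else {
        k <- 1 + rpois(1, max(config$mean_domains_per_gene - 1, 0))
        sample(pool, min(k, length(pool)))
      }
    })
    names(yeast_doms) <- yst

    # hits get significant E-values, plus occasional insignificant decoys
    hit_rows <- function(doms) {
      purrr::imap(doms, function(acc, g) {
        tibble::tibble(
          gene_id = g, accession = acc,
          e_value = 10^runif(length(acc), -30, -4)
        )
      }) |> dplyr::bind_rows()
    }
    domains <- dplyr::bind_rows(hit_rows(human_doms), hit_rows(yeast_doms))
    n_decoy <- ceiling(nrow(domains) * 0.1)
    decoys <- tibble::tibble(
      gene_id = sample(c(hum, yst), n_decoy, replace = TRUE),
      accession = sample(pool, n_decoy, replace = TRUE),
      e_value = 10^runif(n_decoy, -2, 1)  # above any sane cutoff
    )
    domains <- dplyr::bind_rows(domains, decoys) |>
      dplyr::mutate(start = NA_integer_, end = NA_integer_)

    n <- nrow(pair_idx)
    complements <- runif(n) < config$complementation_base_rate
    pid_mean <- config$pid_mean_noncomp +
      ifelse(complements, config$pid_shift_complementing, 0)
    pid <- pmin(pmax(rnorm(n, pid_mean, config$pid_sd), 1), 99)
    pairs <- pair_idx |>
      dplyr::mutate(
        annotated_ortholog = runif(n) < 0.2,
        complements = complements,
        pid = pid
      )

    cutoff <- 0.001
    sig <- significant_domains(domains, cutoff)
    sets <- split(sig$accession, sig$gene_id)
    truth <- pairs |>
      dplyr::mutate(
        human_disease = genes$is_disease_gene[match(.data$human_gene, genes$gene_id)],
        human_clone = genes$clone_available[match(.data$human_gene, genes$gene_id)],
        yeast_essential = genes$is_essential[match(.data$yeast_gene, genes$gene_id)],
        yeast_ts = genes$ts_allele_available[match(.data$yeast_gene, genes$gene_id)],
        covered = purrr::map2_lgl(.data$yeast_gene, .data$human_gene, function(y, h) {
          domain_covered(sets[[y]] %||% character(), sets[[h]] %||% character())
        }),
        should_pass = !.data$annotated_ortholog & .data$human_disease &
          .data$human_clone & .data$yeast_essential & .data$yeast_ts &
          .data$covered
      )

    list(genes = genes, domains = domains, pairs = pairs, truth = truth)
  })
}

# Vectorised FC scoring of a damage vector: the same growth model and
# category arithmetic as simulate_assay() + score_assay(), applied to all
# variants at once. Exact agreement with the per-variant path at zero noise
# is asserted in the test suite.
.sim_fc_batch <- function(damage, config) {
  temps <- config$temperature_panel
  d <- config$dilution_steps
  restrictive <- !(temps %in% config$permissive_temps)
  n <- length(damage)
  tn <- length(temps)
  base <- sim_counts(damage, config)

  mk <- function(level) {
    # rows = temperatures, cols = variants; permissive rows grow fully
    m <- matrix(rep(ifelse(restrictive, 1, NA_real_), n), tn, n)
    m[restrictive, ] <- matrix(rep(level, each = sum(restrictive)),
                               sum(restrictive), n)
    m[!restrictive, ] <- d
    if (config$assay_noise > 0) {
      m <- matrix(rbinom(tn * n, as.integer(m), 1 - config$assay_noise) +
                    rbinom(tn * n, d - as.integer(m), config$assay_noise),
                  tn, n)
      m <- pmin(pmax(m, 0), d)
    }
    m
  }
  test <- mk(base$test)
  wt <- mk(rep(base$wt, n))
  gfp <- mk(rep(base$gfp, n))

  g <- test - gfp
  G <- wt - gfp
  s <- ifelse(G <= 0, NA_real_,
              ifelse(g >= G, 0,
                     ifelse(g >= G / 2, 0.6,
                            ifelse(g > 0, 0.8, 1))))
  evaluable <- colSums(!is.na(s))
  if (any(evaluable == 0)) {
    abort("Simulated assay produced a variant with no evaluable condition.")
  }
  round_half_up(colMeans(s, na.rm = TRUE), 1L)
}

# Restrictive-temperature growth counts for a damage level, before noise:
# gfp grows the baseline, wt rescues wt_rescue spots on top, the test
# plasmid rescues round(wt_rescue * (1 - damage)).
sim_counts <- function(damage, config) {
  list(
    gfp = config$gfp_baseline,
    wt = config$gfp_baseline + config$wt_rescue,
    test = config$gfp_baseline + round(config$wt_rescue * (1 - damage))
  )
}

# flip each of `d` spots with probability `noise`; the first `v` spots are
# visible before noise
flip_spots <- function(v, d, noise) {
  if (noise == 0) return(v)
  rbinom(length(v), v, 1 - noise) + rbinom(length(v), d - v, noise)
}

#' Simulate one spot-assay grid triplet
#'
#' Generates growth grids for the test plasmid and the wild-type and GFP
#' controls of a single variant. At permissive temperatures everything
#' grows fully; at restrictive temperatures the wild-type control rescues
#' `wt_rescue` spots above the GFP baseline and the test plasmid rescues
#' `round(wt_rescue * (1 - damage))` spots before noise. Each spot's
#' visibility then flips independently with probability `assay_noise`.
#'
#' @param damage Latent damage of the variant, in \[0, 1\].
#' @param config A [sim_config()]; its `seed` is *not* applied here so
#'   that batches of variants can share one RNG stream — seed externally
#'   (e.g. [withr::with_seed()]) or via [simulate_variant_table()].
#' @return A list of three grid tibbles (`test`, `wildtype_control`,
#'   `gfp_control`), each with columns `strain_id`, `plasmid`,
#'   `temperature`, `growth`, `dilution_steps`.
#' @export
simulate_assay <- function(damage, config = sim_config()) {
  config <- as_sim_config(config)
  check_prob(damage, "damage")
  temps <- config$temperature_panel
  d <- config$dilution_steps
  restrictive <- !(temps %in% config$permissive_temps)
  base <- sim_counts(damage, config)

  grow <- function(level) {
    v <- ifelse(restrictive, level, d)
    pmin(pmax(flip_spots(v, d, config$assay_noise), 0), d)
  }
  grid <- function(plasmid, level) {
    tibble::tibble(
      strain_id = "sim_strain", plasmid = plasmid,
      temperature = temps, growth = as.integer(grow(level)),
      dilution_steps = d
    )
  }
  list(
    test = grid("test_variant", base$test),
    wildtype_control = grid("wildtype_control", base$wt),
    gfp_control = grid("gfp_control", base$gfp)
  )
}

#' Simulate a scored variant panel with planted ground truth
#'
#' Builds a variant table shaped like the benchmark panel: disease labels
#' are drawn at `frac_disease_variants`; a `frac_damaging_given_disease`
#' share of disease variants (and `frac_damaging_given_benign` of benign
#' ones) receives high latent damage (uniform on \[0.7, 1\], the rest on
#' \[0, 0.1\]). FC scores come from running the spot-assay simulator and
#' the assay scoring rules on every variant; PolyPhen-2-like and
#' PROVEAN-like scores are noisy monotone transforms of the latent damage
#' (Gaussian noise on the logit and on a linear scale respectively).
#'
#' @param config A [sim_config()]; `seed` fully determines the output.
#' @return A list with `variants` (a variant tibble as from
#'   [read_variant_table()]) and `truth` (per-variant latent damage and
#'   damaging flag; never consumed by pipeline stages).
#' @export
simulate_variant_table <- function(config = sim_config()) {
  config <- as_sim_config(config)
  n <- config$n_variants
  if (n < 2) abort("Need at least 2 variants.")
  withr::with_seed(config$seed, {
    disease <- runif(n) < config$frac_disease_variants
    p_damaging <- ifelse(disease, config$frac_damaging_given_disease,
                         config$frac_damaging_given_benign)
    damaging <- runif(n) < p_damaging
    damage <- ifelse(damaging, runif(n, 0.7, 1), runif(n, 0, 0.1))

    fc <- .sim_fc_batch(damage, config)

    dclamp <- pmin(pmax(damage, 0.01), 0.99)
    pph2 <- plogis(qlogis(dclamp) + rnorm(n, 0, config$pph2_noise_sd))
    provean <- 0.5 - 8 * damage + rnorm(n, 0, config$provean_noise_sd)

    ref <- sample(AA20, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(AA20, r), 1), character(1))
    pos <- 1L + (seq_len(n) - 1L) %/% 7L  # unique (gene, position) keys
    gene <- sprintf("SIMG%02d", 1 + (seq_len(n) - 1) %% 7)

    variants <- tibble::tibble(
      gene_symbol = gene,
      entrez_id = 1000L + as.integer(factor(gene)),
      substitution = paste0(ref, pos, alt),
      ref_aa = ref, position = pos, alt_aa = alt,
      disease_associated = disease,
      fc_score = fc,
      pph2_score = pph2,
      provean_score = provean,
      in_aligned_region = runif(n) < 0.5
    )
    truth <- tibble::tibble(
      gene_symbol = gene, substitution = variants$substitution,
      damaging = damaging, latent_damage = damage
    )
    list(variants = variants, truth = truth)
  })
}
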