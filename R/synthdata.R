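#' Simulation configuration
#'
#' Parameters of the synthetic nCounter generator. Defaults emulate the
#' package's reference study design: a 277-gene immune panel with 15
#' housekeeping and 11 colon-specific biological positive-control genes, 6
#' positive spikes (128 down to 0.125 fM), 8 negative probes, 12-lane
#' cartridges carrying 10 study samples each, and three lesion groups
#' (SSL 25, TV 27, TA 48).
#'
#' Count model: negatives are Poisson with mean `lambda0`; positive spikes
#' are Poisson with mean `kappa * conc * s_i` (lane efficiency `s_i`);
#' biological probes are `Poisson(lambda0)` background plus a
#' negative-binomial signal with mean
#' `s_i * b_c * 2^(mu_g + delta_g(group) + outlier shift)` and dispersion
#' `phi_g`. Lane efficiency and cartridge batch multipliers are drawn
#' uniformly on bounded log2 ranges — technical variation on this platform is
#' bounded in practice, and bounded noise keeps the interquartile-range QC
#' fences free of chance tail exclusions, so that QC outcomes are determined
#' by planted anomalies rather than by tail luck.
#'
#' FFPE-style degradation is modelled as binomial thinning of a degraded
#' sample's counts: strong thinning (`attenuation`, log2 scale) of the
#' degradation-sensitive panel (by default the biological positive-control
#' genes, chosen for their sensitivity to fragmentation) and mild thinning
#' (`global_attenuation`) of all other biological probes. Spike-in probes
#' are never attenuated: degradation destroys endogenous RNA while technical
#' controls still pass. Outlier samples receive a global log2 shift on
#' biological probes.
#'
#' @param n_endogenous,n_housekeeping,n_bio_positive,n_neg_spike panel sizes
#' @param pos_concentrations positive spike concentrations, fM, decreasing
#' @param group_sizes named integer vector of cohort group sizes
#' @param samples_per_cartridge study samples per 12-lane cartridge
#' @param baseline_log2_endog,baseline_log2_hk,baseline_log2_bio ranges of
#'   per-gene baseline log2 means
#' @param phi_range range of per-gene NB dispersions
#' @param size_log2_half_range lane efficiency: log2 s_i ~ U(-r, r)
#' @param batch_log2_half_range cartridge batch: log2 b_c ~ U(-r, r)
#' @param n_latent number of latent biological composition axes (e.g.
#'   epithelial vs. immune content); per-sample scores are uniform on
#'   `[-1, 1]`, per-gene loadings Gaussian with sd `latent_loading_sd`,
#'   applied to endogenous genes only (housekeeping genes are stable by
#'   definition and the positive-control panel is chosen for universal
#'   expression)
#' @param latent_loading_sd log2-scale loading sd of the composition axes
#' @param lambda0 background Poisson mean (counts)
#' @param kappa spike gain, counts per fM at s = 1 (default puts the 128 fM
#'   spike near 20,000 counts)
#' @param de data frame with columns `gene`, `group`, `log2FC`: planted
#'   effects (referenced to the baseline; empty by default)
#' @param n_degraded number of degraded samples
#' @param degraded_by_group optional named vector allocating degraded samples
#'   to groups
#' @param attenuation strong log2 thinning of the sensitive panel (negative)
#' @param global_attenuation mild log2 thinning of other biological probes
#' @param n_outliers number of global-shift outlier samples
#' @param outlier_by_group optional named allocation of outliers
#' @param outlier_shift log2 shift applied to outlier samples
#' @param seed RNG seed
#' @return a list of class `ncx_sim_config`
#' @export
sim_config <- function(n_endogenous = 277L, n_housekeeping = 15L,
                       n_bio_positive = 11L,
                       pos_concentrations = c(128, 32, 8, 2, 0.5, 0.125),
                       n_neg_spike = 8L,
                       group_sizes = c(SSL = 25L, TV = 27L, TA = 48L),
                       samples_per_cartridge = 10L,
                       baseline_log2_endog = c(5, 10),
                       baseline_log2_hk = c(6, 9),
                       baseline_log2_bio = c(6, 7.5),
                       phi_range = c(0.05, 0.15),
                       size_log2_half_range = 0.8,
                       batch_log2_half_range = 0.7,
                       n_latent = 2L,
                       latent_loading_sd = 0.7,
                       lambda0 = 10,
                       kappa = 20000 / 128,
                       de = NULL,
                       n_degraded = 0L, degraded_by_group = NULL,
                       attenuation = -5.5, global_attenuation = -0.3,
                       n_outliers = 0L, outlier_by_group = NULL,
                       outlier_shift = 5,
                       seed = 1L) {
  stopifnot(n_endogenous >= 1, n_housekeeping >= 1, n_bio_positive >= 0,
            n_neg_spike >= 1, all(diff(pos_concentrations) < 0),
            all(pos_concentrations > 0), all(group_sizes >= 0),
            lambda0 >= 0, kappa > 0, phi_range[1] >= 0,
            size_log2_half_range >= 0, batch_log2_half_range >= 0,
            n_latent >= 0, latent_loading_sd >= 0,
            attenuation <= 0, global_attenuation <= 0,
            n_degraded >= 0, n_outliers >= 0,
            n_degraded + n_outliers <= sum(group_sizes))
  if (is.null(names(group_sizes))) {
    abort("`group_sizes` must be a named vector.")
  }
  structure(as.list(environment()), class = "ncx_sim_config")
}

sim_gene_table <- function(cfg) {
  codeset <- load_packaged_codeset()
  bio <- if (cfg$n_bio_positive == length(codeset$bio_positive)) {
    codeset$bio_positive
  } else if (cfg$n_bio_positive > 0) {
    sprintf("BIO%02d", seq_len(cfg$n_bio_positive))
  } else character()
  hk <- if (cfg$n_housekeeping == length(codeset$housekeeping)) {
    codeset$housekeeping
  } else sprintf("HK%02d", seq_len(cfg$n_housekeeping))
  endo <- sprintf("IMM%03d", seq_len(cfg$n_endogenous))
  pos <- sprintf("POS_%s(%g)", LETTERS[seq_along(cfg$pos_concentrations)],
                 cfg$pos_concentrations)
  neg <- sprintf("NEG_%s", LETTERS[seq_len(cfg$n_neg_spike)])
  tibble::tibble(
    probe = c(endo, bio, hk, pos, neg),
    class = rep(c("ENDOGENOUS", "BIO_POSITIVE", "HOUSEKEEPING",
                  "POSITIVE_SPIKE", "NEGATIVE_SPIKE"),
                c(length(endo), length(bio), length(hk), length(pos),
                  length(neg))),
    accession = NA_character_,
    spike_fM = c(rep(NA, length(endo) + length(bio) + length(hk)),
                 cfg$pos_concentrations, rep(NA, length(neg))))
}

# deterministic allocation of n flagged samples across groups,
# proportionally to group size (largest remainder)
alloc_by_group <- function(n, group_sizes) {
  if (n == 0) return(setNames(rep(0L, length(group_sizes)),
                              names(group_sizes)))
  raw <- n * group_sizes / sum(group_sizes)
  base <- floor(raw)
  rem <- n - sum(base)
  extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
  base[extra] <- base[extra] + 1
  setNames(as.integer(base), names(group_sizes))
}

#' Simulate a synthetic nCounter experiment
#'
#' Draws a full experiment (counts, probe annotation, sample metadata with
#' lane attributes) from the generative model described in [sim_config()],
#' together with the ground truth of every latent quantity.
#'
#' @param cfg a [sim_config()]
#' @return a list with elements `experiment` (an [experiment()]) and `truth`
#'   (list: `samples` tibble with per-sample latent size factor, batch,
#'   degraded/outlier flags; `genes` tibble with baselines and dispersions;
#'   `de` the planted effect table)
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "ncx_sim_config"))
  set.seed(cfg$seed)
  genes <- sim_gene_table(cfg)
  bio_all <- genes$probe[genes$class %in% bio_probe_classes]
  sensitive <- genes$probe[genes$class == "BIO_POSITIVE"]

  de <- if (is.null(cfg$de)) {
    tibble::tibble(gene = character(), group = character(),
                   log2FC = numeric())
  } else tibble::as_tibble(cfg$de)
  bad_de <- setdiff(de$gene,
                    genes$probe[genes$class %in% c("ENDOGENOUS",
                                                   "BIO_POSITIVE")])
  if (length(bad_de)) {
    abort(paste0("Planted effects may only target endogenous or biological ",
                 "positive-control genes, not: ",
                 paste(bad_de, collapse = ", ")))
  }

  n <- sum(cfg$group_sizes)
  group <- rep(names(cfg$group_sizes), cfg$group_sizes)
  ids <- sprintf("S%03d", seq_len(n))
  n_cart <- ceiling(n / cfg$samples_per_cartridge)
  # stratified round-robin: each group's samples continue one global cycle
  # through the cartridges, so every group is spread evenly and cartridge
  # loads stay balanced
  cart <- integer(n)
  pos <- 0L
  for (g in names(cfg$group_sizes)) {
    idx <- which(group == g)
    cart[idx] <- (pos + seq_along(idx) - 1L) %% n_cart + 1L
    pos <- pos + length(idx)
  }
  cartridge <- sprintf("C%02d", cart)

  # per-gene latents
  gt <- genes[genes$class %in% bio_probe_classes, ]
  rng <- list(ENDOGENOUS = cfg$baseline_log2_endog,
              HOUSEKEEPING = cfg$baseline_log2_hk,
              BIO_POSITIVE = cfg$baseline_log2_bio)
  mu <- vapply(seq_len(nrow(gt)), function(i) {
    r <- rng[[gt$class[i]]]
    runif(1, r[1], r[2])
  }, 1.0)
  phi <- runif(nrow(gt), cfg$phi_range[1], cfg$phi_range[2])
  names(mu) <- names(phi) <- gt$probe

  # per-sample latents
  s_log2 <- runif(n, -cfg$size_log2_half_range, cfg$size_log2_half_range)
  b_log2_cart <- runif(n_cart, -cfg$batch_log2_half_range,
                       cfg$batch_log2_half_range)
  b_log2 <- b_log2_cart[cart]

  pick_flag <- function(total, by_group) {
    if (is.null(by_group)) by_group <- alloc_by_group(total, cfg$group_sizes)
    flags <- rep(FALSE, n)
    for (g in names(by_group)) {
      cand <- which(group == g & !flags)
      if (by_group[[g]] > 0) {
        flags[sample(cand, by_group[[g]])] <- TRUE
      }
    }
    flags
  }
  outlier <- pick_flag(cfg$n_outliers, cfg$outlier_by_group)
  avail <- !outlier
  degraded <- rep(FALSE, n)
  if (cfg$n_degraded > 0) {
    by_group <- cfg$degraded_by_group %||%
      alloc_by_group(cfg$n_degraded, cfg$group_sizes)
    for (g in names(by_group)) {
      cand <- which(group == g & avail)
      if (by_group[[g]] > 0) degraded[sample(cand, by_group[[g]])] <- TRUE
    }
  }

  # planted effect matrix (genes x samples, log2)
  delta <- matrix(0, nrow(gt), n, dimnames = list(gt$probe, ids))
  if (nrow(de)) {
    for (i in seq_len(nrow(de))) {
      delta[de$gene[i], group == de$group[i]] <-
        delta[de$gene[i], group == de$group[i]] + de$log2FC[i]
    }
  }

  # counts
  counts <- matrix(0, nrow(genes), n, dimnames = list(genes$probe, ids))
  is_neg <- genes$class == "NEGATIVE_SPIKE"
  counts[is_neg, ] <- rpois(sum(is_neg) * n, cfg$lambda0)
  is_pos <- genes$class == "POSITIVE_SPIKE"
  pos_mean <- outer(cfg$kappa * genes$spike_fM[is_pos], 2^s_log2)
  counts[is_pos, ] <- rpois(length(pos_mean), pos_mean)

  shift <- matrix(rep(s_log2 + b_log2 + cfg$outlier_shift * outlier,
                      each = nrow(gt)), nrow(gt), n)
  # bounded biological composition axes on endogenous genes
  latent_scores <- matrix(0, cfg$n_latent, n)
  if (cfg$n_latent > 0) {
    loadings <- matrix(0, nrow(gt), cfg$n_latent,
                       dimnames = list(gt$probe, NULL))
    is_endo <- gt$class == "ENDOGENOUS"
    loadings[is_endo, ] <- rnorm(sum(is_endo) * cfg$n_latent,
                                 sd = cfg$latent_loading_sd)
    latent_scores[] <- runif(cfg$n_latent * n, -1, 1)
    shift <- shift + loadings %*% latent_scores
  }
  mean_bio <- 2^(mu + delta + shift)
  signal <- matrix(rnbinom(length(mean_bio), mu = mean_bio,
                           size = 1 / pmax(phi, 1e-8)),
                   nrow(gt), n, dimnames = dimnames(mean_bio))
  background <- matrix(rpois(length(mean_bio), cfg$lambda0), nrow(gt), n)
  bio_counts <- signal + background

  # degradation: binomial thinning of the degraded samples' counts
  if (any(degraded)) {
    p_strong <- 2^cfg$attenuation
    p_mild <- 2^cfg$global_attenuation
    for (j in which(degraded)) {
      strong <- rownames(bio_counts) %in% sensitive
      bio_counts[strong, j] <-
        stats::rbinom(sum(strong), bio_counts[strong, j], p_strong)
      bio_counts[!strong, j] <-
        stats::rbinom(sum(!strong), bio_counts[!strong, j], p_mild)
    }
  }
  counts[rownames(bio_counts), ] <- bio_counts

  samples <- tibble::tibble(
    sample_id = ids, group = group, cartridge = cartridge,
    size_mm = round(pmax(rnorm(n, 9, 4), 2), 1),
    age = round(runif(n, 40, 75)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    lane_id = as.character(stats::ave(seq_len(n), cart, FUN = seq_along)),
    fov_count = 555,
    fov_counted = round(555 * runif(n, 0.96, 1)),
    binding_density = round(runif(n, 0.5, 2.0), 3))

  exp <- experiment(counts, genes, samples)
  truth_samples <- tibble::tibble(
    sample_id = ids, group = group, cartridge = cartridge,
    size_log2 = s_log2, batch_log2 = b_log2,
    degraded = degraded, outlier = outlier)
  if (cfg$n_latent > 0) {
    lat <- tibble::as_tibble(t(latent_scores), .name_repair = "minimal")
    names(lat) <- paste0("latent", seq_len(cfg$n_latent))
    truth_samples <- dplyr::bind_cols(truth_samples, lat)
  }
  truth <- list(
    samples = truth_samples,
    genes = tibble::tibble(gene = gt$probe, class = gt$class,
                           baseline_log2 = unname(mu),
                           phi = unname(phi)),
    de = de)
  list(experiment = exp, truth = truth)
}

#' Simulate an exchangeable null experiment
#'
#' [simulate_experiment()] with no planted effects, degradation or outliers:
#' group labels are attached but exchangeable by construction, the setting
#' required by the permutation Type I error simulation.
#'
#' @param cfg a [sim_config()]; any planted structure in it is stripped
#' @return as [simulate_experiment()]
#' @export
null_experiment <- function(cfg = sim_config()) {
  cfg$de <- NULL
  cfg$n_degraded <- 0L
  cfg$n_outliers <- 0L
  cfg$degraded_by_group <- NULL
  cfg$outlier_by_group <- NULL
  simulate_experiment(cfg)
}

#' The reference synthetic cohort
#'
#' Convenience preset mirroring the package's motivating study design: 100
#' samples (SSL 25, TV 27, TA 48) on 10 cartridges, 2 planted global-shift
#' outliers, 11 planted degraded samples (allocated 4/3/6 to SSL/TV/TA
#' together with the outliers, the flag distribution of the reference
#' cohort), and planted differential expression: a mucin-program analog
#' (over-expressed in SSL, including several biological positive-control
#' genes), a WNT-program analog (under-expressed in SSL), and
#' under-expression only in TV.
#'
#' @param seed RNG seed
#' @return as [simulate_experiment()]
#' @export
paper_like_cohort <- function(seed = 1L) {
  mucin_up <- sprintf("IMM%03d", 1:26)
  wnt_down <- sprintf("IMM%03d", 27:50)
  tv_down <- sprintf("IMM%03d", 31:55)
  de <- dplyr::bind_rows(
    tibble::tibble(gene = mucin_up, group = "SSL", log2FC = 1.5),
    tibble::tibble(gene = c("TFF1", "MUC5AC", "MUC2", "CDH1"),
                   group = "SSL", log2FC = c(1.5, 1.5, 1.2, 0.8)),
    tibble::tibble(gene = wnt_down, group = "SSL", log2FC = -1.2),
    tibble::tibble(gene = c("ITLN1", "OLFM4", "SELENBP1"),
                   group = "SSL", log2FC = c(-1.2, -1.2, -1.0)),
    tibble::tibble(gene = tv_down, group = "TV", log2FC = -1.0))
  cfg <- sim_config(
    de = de,
    n_degraded = 11L,
    degraded_by_group = c(SSL = 3L, TV = 3L, TA = 5L),
    n_outliers = 2L,
    outlier_by_group = c(SSL = 1L, TV = 0L, TA = 1L),
    seed = seed)
  simulate_experiment(cfg)
}
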