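#' Configuration of a simulated FMT trial
#'
#' Defaults mirror a small placebo-controlled oral-FMT trial in dogs with
#' tylosin-responsive enteropathy: 7 FMT and 7 placebo recipients, a
#' single stool donor sampled twice, a 30-dog healthy reference cohort,
#' roughly 60 donor-specific ASVs each transferring independently with
#' probability 0.30, and clinical trajectories with a linear fecal
#' consistency / dry matter link (FCS = 5 - 0.09 FDM + noise).
#'
#' @param n_fmt,n_placebo,n_healthy cohort sizes
#' @param n_donor_asvs donor-specific ASVs (the engraftment candidates)
#' @param n_background_asvs ASVs of the shared background community
#' @param overlap_fraction fraction of background ASVs also carried by
#'   the donor (default 0: donor-specific ASVs are disjoint from the
#'   background so engraftment ground truth is unambiguous; raise it to
#'   stress the pre-FMT exclusion logic)
#' @param n_donor_samples donor fecal lots sequenced
#' @param engraft_prob per-candidate-ASV transfer probability
#' @param transfer_floor minimum relative abundance of a transferred ASV,
#'   as a multiple of 1/depth (default 5, making post-FMT detection
#'   near-certain at the default depth)
#' @param sequencing_depth reads per sample
#' @param dysbiosis_severity divisor applied to the Dirichlet
#'   concentrations of recipient pre-FMT communities; larger values give
#'   spikier, less even communities (default 4)
#' @param relapse_prob named numeric vector of per-phase relapse
#'   probabilities: `fmt_treatment`, `fmt_post`, `placebo_treatment`,
#'   `placebo_post`
#' @param fcs_fdm_slope,fcs_intercept linear FCS-FDM link
#' @param fcs_noise_sd residual SD of FCS around the link
#' @param fdm_mean,fdm_sd normal distribution of FDM%
#' @param seed integer seed; every source of randomness in the generator
#'   flows from it
#' @return a `trial_sim_config` list
#' @export
trial_sim_config <- function(n_fmt = 7, n_placebo = 7, n_healthy = 30,
                             n_donor_asvs = 60, n_background_asvs = 240,
                             overlap_fraction = 0, n_donor_samples = 2,
                             engraft_prob = 0.30, transfer_floor = 5,
                             sequencing_depth = 20000,
                             dysbiosis_severity = 4,
                             relapse_prob = c(fmt_treatment = 2 / 7,
                                              fmt_post = 0.5,
                                              placebo_treatment = 0.5,
                                              placebo_post = 0),
                             fcs_fdm_slope = -0.09, fcs_intercept = 5,
                             fcs_noise_sd = 0.397,
                             fdm_mean = 35, fdm_sd = 5,
                             seed = 1) {
  stopifnot(engraft_prob >= 0, engraft_prob <= 1,
            all(relapse_prob >= 0 & relapse_prob <= 1),
            sequencing_depth >= 1, n_donor_asvs >= 5,
            overlap_fraction >= 0, overlap_fraction <= 1,
            dysbiosis_severity >= 0, fcs_noise_sd > 0)
  needed <- c("fmt_treatment", "fmt_post", "placebo_treatment",
              "placebo_post")
  if (!all(needed %in% names(relapse_prob)))
    stop("relapse_prob must name: ", paste(needed, collapse = ", "))
  structure(as.list(environment()), class = "trial_sim_config")
}

sim_asv_ids <- function(config) {
  list(donor = sprintf("ASVd%03d", seq_len(config$n_donor_asvs)),
       background = sprintf("ASVb%03d", seq_len(config$n_background_asvs)))
}

# long-tailed concentration vector: a few dominant taxa, many rare ones
longtail_alpha <- function(k, top = 10) {
  alpha <- 2 / seq_len(k)^0.9
  alpha[1L] <- top
  alpha
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  names(g) <- names(alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate the donor community
#'
#' A Dirichlet draw over the donor-specific ASVs (plus an optional
#' overlapping slice of the background) with one dominant taxon and a
#' long tail, emulating a healthy donor dominated by a single abundant
#' species.  Deterministic given `config$seed`.
#'
#' @param config a [trial_sim_config()]
#' @return object of class `community_profile`: `taxon_ids`, `alpha`
#'   (concentrations), `proportions`
#' @export
simulate_donor <- function(config) {
  stopifnot(inherits(config, "trial_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  .simulate_donor(config)
}

.simulate_donor <- function(config) {
  ids <- sim_asv_ids(config)
  n_shared <- floor(config$overlap_fraction * config$n_background_asvs)
  # shared slice = the most abundant background taxa, so overlap ASVs are
  # reliably present in recipients pre-FMT and exercised by the exclusion
  taxa <- c(ids$donor, ids$background[seq_len(n_shared)])
  alpha <- longtail_alpha(length(taxa))
  p <- stats::setNames(rdirichlet1(alpha), taxa)
  # floor the tail so every donor ASV sits comfortably above the
  # detection limit of the configured depth (and survives dataset-wide
  # singleton/doubleton removal); the long-tailed shape is kept above it
  p <- pmax(p, 2 * config$transfer_floor / config$sequencing_depth)
  p <- p / sum(p)
  structure(list(taxon_ids = taxa, alpha = alpha, proportions = p),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf("community_profile: %d taxa, top %s (%.1f%%)\n",
              length(x$taxon_ids), names(which.max(x$proportions)),
              100 * max(x$proportions)))
  invisible(x)
}

#' Multinomial read counts from a community profile
#'
#' @param profile a `community_profile` (or bare named proportion vector)
#' @param depth total reads to draw; the returned counts sum to `depth`
#'   exactly
#' @param seed optional seed; when omitted the current RNG stream is used
#' @return named integer count vector
#' @export
simulate_counts <- function(profile, depth, seed = NULL) {
  stopifnot(depth >= 1)
  p <- if (inherits(profile, "community_profile")) profile$proportions
  else profile
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  stats::setNames(as.integer(stats::rmultinom(1, size = depth, prob = p)),
                  names(p))
}

#' Simulate one recipient's visit-by-visit community timeline
#'
#' Pre-FMT visits (screening, inclusion, endoscopy) are drawn from a
#' dysbiotic background community (concentrations divided by
#' `dysbiosis_severity + 1`, lowering evenness relative to healthy dogs).
#' For FMT dogs, post visits (treatment, post-treatment) mix the pre
#' community with the donor-specific ASVs, each transferred independently
#' with probability `engraft_prob` at a relative abundance of at least
#' `transfer_floor / sequencing_depth`; placebo dogs get drift-only
#' redraws from their pre-FMT concentrations.  The truly transferred set
#' is recorded as ground truth.
#'
#' @param donor the donor `community_profile`
#' @param config a [trial_sim_config()]
#' @param dog_index recipient index (used only for labelling)
#' @param group `"FMT"` or `"placebo"`
#' @return list with `visits` (named list of proportion vectors over all
#'   simulated taxa) and `transferred` (character vector of donor ASV
#'   ids; empty for placebo)
#' @export
simulate_recipient_timeline <- function(donor, config, dog_index,
                                        group = c("FMT", "placebo")) {
  group <- match.arg(group)
  ids <- sim_asv_ids(config)
  all_taxa <- unique(c(ids$donor, ids$background))
  bg_alpha <- stats::setNames(longtail_alpha(length(ids$background)),
                              ids$background)
  dys_alpha <- bg_alpha / (config$dysbiosis_severity + 1)
  expand <- function(p) {
    full <- stats::setNames(numeric(length(all_taxa)), all_taxa)
    full[names(p)] <- p
    full
  }
  pre_visits <- lapply(c(screening = 1, inclusion = 2, endoscopy = 3),
                       function(i) expand(rdirichlet1(dys_alpha)))
  transferred <- character(0)
  if (group == "FMT") {
    transferred <- ids$donor[stats::runif(length(ids$donor)) <
                               config$engraft_prob]
    floor_ab <- config$transfer_floor / config$sequencing_depth
    donor_p <- donor$proportions[transferred]
    graft <- pmax(donor_p, floor_ab)
    post_visits <- lapply(c(treatment = 1, post_treatment = 2),
                          function(i) {
      base <- expand(rdirichlet1(dys_alpha * 2))  # partial recovery
      base[transferred] <- graft
      base / sum(base)
    })
  } else {
    post_visits <- lapply(c(treatment = 1, post_treatment = 2),
                          function(i) expand(rdirichlet1(dys_alpha * 2)))
  }
  list(visits = c(pre_visits, post_visits), transferred = transferred)
}

#' Simulate clinical trajectories for the trial
#'
#' Per dog and phase, relapse is drawn with the configured probability;
#' CCECAI items are drawn so that relapsed dogs total above 3 and
#' responders stay at 3 or below; FDM% is normal and FCS follows the
#' linear link `fcs_intercept + fcs_fdm_slope * FDM + noise`, clipped to
#' the 1-5 half-point grid for diary entries (the unclipped pairs are
#' retained for regression analyses).
#'
#' @param config a [trial_sim_config()]
#' @param use_seed set the RNG from `config$seed` (default TRUE; internal
#'   callers that already manage the stream pass FALSE)
#' @return list of data frames: `disposition`, `ccecai`, `fcs_diary`,
#'   `fdm`, `regression_pairs`, plus `ground_truth` (per-dog latent
#'   relapse states)
#' @export
simulate_clinical <- function(config, use_seed = TRUE) {
  stopifnot(inherits(config, "trial_sim_config"))
  if (use_seed) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(config$seed + 1L)
  }
  dogs <- data.frame(
    dog_id = c(sprintf("fmt%02d", seq_len(config$n_fmt)),
               sprintf("plc%02d", seq_len(config$n_placebo))),
    group = rep(c("FMT", "placebo"), c(config$n_fmt, config$n_placebo)),
    stringsAsFactors = FALSE)
  rp <- config$relapse_prob
  disposition <- list(); ccecai <- list(); diary <- list()
  fdm <- list(); pairs <- list(); latent <- list()
  day0 <- 0L
  draw_items <- function(total_target) {
    # spread a target total over nine 0-3 items
    items <- integer(9)
    left <- total_target
    for (i in sample(9)) {
      take <- min(3L, left)
      items[i] <- sample(0:take, 1)
      left <- left - items[i]
      if (left == 0) break
    }
    if (left > 0) {  # cap overflow onto remaining items
      for (i in seq_len(9)) {
        add <- min(3L - items[i], left)
        items[i] <- items[i] + add
        left <- left - add
        if (left == 0) break
      }
    }
    items
  }
  for (k in seq_len(nrow(dogs))) {
    dog <- dogs$dog_id[k]
    grp <- dogs$group[k]
    key <- if (grp == "FMT") c("fmt_treatment", "fmt_post")
    else c("placebo_treatment", "placebo_post")
    rel_treat <- stats::runif(1) < rp[[key[1L]]]
    rel_post <- !rel_treat && stats::runif(1) < rp[[key[2L]]]
    latent[[dog]] <- list(treatment = rel_treat, post_treatment = rel_post)
    disposition[[paste(dog, "t")]] <- data.frame(
      dog_id = dog, group = grp, phase = "treatment",
      status = if (rel_treat) "relapsed" else "responder",
      exclusion_reason = "", stringsAsFactors = FALSE)
    if (!rel_treat)
      disposition[[paste(dog, "p")]] <- data.frame(
        dog_id = dog, group = grp, phase = "post_treatment",
        status = if (rel_post) "relapsed" else "responder",
        exclusion_reason = "", stringsAsFactors = FALSE)
    for (ph in c("treatment", "post_treatment")) {
      if (ph == "post_treatment" && rel_treat) next
      relapsed <- if (ph == "treatment") rel_treat else rel_post
      total <- if (relapsed) sample(4:12, 1) else sample(0:3, 1)
      items <- draw_items(total)
      ccecai[[paste(dog, ph)]] <- data.frame(
        dog_id = dog, visit = ph,
        as.list(stats::setNames(items, CCECAI_ITEMS)),
        stringsAsFactors = FALSE)
      # 3-day diary window + duplicate FDM measurement at the visit
      for (day in 1:3) {
        fdm_val <- stats::rnorm(1, config$fdm_mean, config$fdm_sd)
        fcs_raw <- config$fcs_intercept +
          config$fcs_fdm_slope * fdm_val +
          stats::rnorm(1, 0, config$fcs_noise_sd)
        fcs_clip <- min(5, max(1, round(fcs_raw * 2) / 2))
        diary[[paste(dog, ph, day)]] <- data.frame(
          dog_id = dog, phase = ph, day = day0 + day, fcs = fcs_clip,
          stringsAsFactors = FALSE)
        pairs[[paste(dog, ph, day)]] <- data.frame(
          dog_id = dog, fdm_percent = fdm_val, fcs = fcs_raw,
          stringsAsFactors = FALSE)
      }
      wet <- stats::runif(2, 0.4, 0.6)
      dry <- wet * stats::rnorm(2, fdm_val, 0.5) / 100
      dry <- pmin(pmax(dry, 0), wet)
      fdm[[paste(dog, ph)]] <- data.frame(
        dog_id = dog, visit = ph, wet1 = wet[1L], dry1 = dry[1L],
        wet2 = wet[2L], dry2 = dry[2L], stringsAsFactors = FALSE)
    }
    day0 <- day0 + 10L
  }
  list(disposition = do.call(rbind, c(disposition,
                                      make.row.names = FALSE)),
       ccecai = do.call(rbind, c(ccecai, make.row.names = FALSE)),
       fcs_diary = do.call(rbind, c(diary, make.row.names = FALSE)),
       fdm = do.call(rbind, c(fdm, make.row.names = FALSE)),
       regression_pairs = do.call(rbind, c(pairs,
                                           make.row.names = FALSE)),
       ground_truth = latent)
}

#' Simulate FCS-FDM pairs from the linear link
#'
#' Stand-alone draw of `n` (FDM%, FCS) pairs from the generator's default
#' link, used for regression calibration checks.
#'
#' @param n number of pairs
#' @param config a [trial_sim_config()] (link parameters are read from it)
#' @param seed RNG seed
#' @return data frame with columns `fdm_percent`, `fcs`
#' @export
simulate_fcs_fdm_pairs <- function(n = 500, config = trial_sim_config(),
                                   seed = config$seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fdm <- stats::rnorm(n, config$fdm_mean, config$fdm_sd)
  fcs <- config$fcs_intercept + config$fcs_fdm_slope * fdm +
    stats::rnorm(n, 0, config$fcs_noise_sd)
  data.frame(fdm_percent = fdm, fcs = fcs)
}

#' Generate a complete simulated trial dataset
#'
#' Produces internally consistent inputs for every pipeline stage: the
#' ASV count table over donor lots, recipient visits and the healthy
#' cohort, a taxonomy, sample metadata, clinical CSVs and the ground
#' truth (per-recipient transferred ASV sets, the configured transfer
#' probability, and latent clinical states).  Deterministic given
#' `config$seed`; when `out_dir` is given the bundle is also written to
#' disk in the formats the reader functions consume.
#'
#' @param config a [trial_sim_config()]
#' @param out_dir optional directory to write the bundle into
#' @return list with `table` ([asv_table()]), `metadata`, `clinical`
#'   (see [simulate_clinical()]), `ground_truth`
#' @export
make_fixture_dataset <- function(config = trial_sim_config(),
                                 out_dir = NULL) {
  stopifnot(inherits(config, "trial_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  ids <- sim_asv_ids(config)
  all_taxa <- unique(c(ids$donor, ids$background))
  donor <- .simulate_donor(config)
  depth <- config$sequencing_depth
  counts <- list()
  meta <- list()
  expand <- function(p) {
    full <- stats::setNames(numeric(length(all_taxa)), all_taxa)
    full[names(p)] <- p
    full
  }
  for (j in seq_len(config$n_donor_samples)) {
    sid <- sprintf("donor_s%02d", j)
    counts[[sid]] <- simulate_counts(expand(donor$proportions), depth)
    meta[[sid]] <- data.frame(sample_id = sid, dog_id = "donor",
                              group = "donor", visit = "donor",
                              stringsAsFactors = FALSE)
  }
  transferred <- list()
  dogs <- data.frame(
    dog_id = c(sprintf("fmt%02d", seq_len(config$n_fmt)),
               sprintf("plc%02d", seq_len(config$n_placebo))),
    group = rep(c("FMT", "placebo"), c(config$n_fmt, config$n_placebo)),
    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(dogs))) {
    tl <- simulate_recipient_timeline(donor, config, k, dogs$group[k])
    transferred[[dogs$dog_id[k]]] <- tl$transferred
    for (v in names(tl$visits)) {
      sid <- paste(dogs$dog_id[k], v, sep = "_")
      counts[[sid]] <- simulate_counts(tl$visits[[v]], depth)
      meta[[sid]] <- data.frame(sample_id = sid, dog_id = dogs$dog_id[k],
                                group = dogs$group[k], visit = v,
                                stringsAsFactors = FALSE)
    }
  }
  healthy_alpha <- stats::setNames(longtail_alpha(length(ids$background)),
                                   ids$background)
  for (h in seq_len(config$n_healthy)) {
    sid <- sprintf("healthy%02d", h)
    counts[[sid]] <- simulate_counts(expand(rdirichlet1(healthy_alpha)),
                                     depth)
    meta[[sid]] <- data.frame(sample_id = sid, dog_id = sid,
                              group = "healthy", visit = "healthy",
                              stringsAsFactors = FALSE)
  }
  mat <- do.call(rbind, counts)
  metadata <- do.call(rbind, c(meta, make.row.names = FALSE))
  taxonomy <- sim_taxonomy(all_taxa)
  table <- asv_table(mat, taxonomy = taxonomy)
  clinical <- simulate_clinical(config, use_seed = FALSE)
  ground_truth <- list(engraft_prob = config$engraft_prob,
                       transferred = transferred,
                       clinical = clinical$ground_truth)
  out <- list(table = table, metadata = metadata, clinical = clinical,
              ground_truth = ground_truth, config = config)
  if (!is.null(out_dir)) write_fixture_bundle(out, out_dir)
  out
}

# invented but field-plausible labels; donor ASVs get distinct species so
# per-ASV engraftment frequencies are readable
sim_taxonomy <- function(taxa) {
  genera <- c("Blautia", "Ruminococcus", "Clostridium", "Megamonas",
              "Prevotella", "Fusobacterium", "Streptococcus",
              "Collinsella", "Peptoclostridium", "Bacteroides",
              "Romboutsia", "Terrisporobacter", "Enterococcus",
              "Escherichia", "Lachnoclostridium", "Turicibacter",
              "Faecalibacterium", "Butyricicoccus", "Faecalimonas",
              "Fournierella", "Catenibacterium", "Holdemanella",
              "Sutterella", "Allobaculum", "Dubosiella",
              "Phascolarctobacterium", "Megasphaera", "Anaerostipes",
              "Coprococcus", "Roseburia")
  g <- genera[(seq_along(taxa) - 1L) %% length(genera) + 1L]
  data.frame(
    asv_id = taxa,
    domain = "Bacteria", phylum = "Firmicutes", class = "Clostridia",
    order = "Lachnospirales", family = "Lachnospiraceae",
    genus = g,
    species = paste0(g, " sp", seq_along(taxa)),
    stringsAsFactors = FALSE)
}

write_fixture_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_asv_table(bundle$table, file.path(out_dir, "feature_table.tsv"))
  write_taxonomy(bundle$table$taxonomy, file.path(out_dir, "taxonomy.tsv"))
  write_metadata(bundle$metadata, file.path(out_dir, "metadata.tsv"))
  cl <- bundle$clinical
  utils::write.csv(cl$disposition, file.path(out_dir, "disposition.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cl$ccecai, file.path(out_dir, "ccecai.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cl$fcs_diary, file.path(out_dir, "fcs_diary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cl$fdm, file.path(out_dir, "fdm.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cl$regression_pairs,
                   file.path(out_dir, "regression_pairs.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(engraft_prob = bundle$ground_truth$engraft_prob,
         transferred = bundle$ground_truth$transferred,
         clinical = bundle$ground_truth$clinical),
    file.path(out_dir, "ground_truth.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
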