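# Synthetic cohorts with the statistical structure the clonality
# analysis assumes: patients with related (clonally descended) or
# unrelated lesion pairs, trunk mutations and copy-number events shared
# by related partners, array noise, and GC-biased exome coverage.
# Everything downstream is testable against the planted ground truth.

#' Simulation configuration
#'
#' Defaults describe a realistic multifocal-LCIS mastectomy cohort:
#' patients contribute 2-3 lesions with negative-binomial mutation
#' burdens around a median of ~33, occasional hypermutated lesions, a
#' mutation catalog with two dominant hotspot genes (CDH1- and
#' PIK3CA-like) over a power-law tail, arm-event priors with two
#' ubiquitous events (1q-gain-like and 16q-loss-like), and noisy
#' 200-600-probe arms on a toy 8-arm genome.
#'
#' @param n_patients number of patients.
#' @param lesions_per_patient inclusive range (length-2) of lesions drawn
#'   per patient.
#' @param clonal_fraction probability that a patient's lesions are
#'   clonally related.
#' @param xi clonality fraction of related pairs: the fraction of a
#'   lesion's mutation burden inherited from the shared trunk.
#' @param burden_mean,burden_size negative-binomial mutation burden per
#'   lesion (mean/size).
#' @param hyper_prob,hyper_burden probability a lesion is hypermutated
#'   and its burden then.
#' @param catalog_size number of distinct mutation loci in the catalog.
#' @param n_genes number of genes carrying the catalog.
#' @param hotspot_counts reference-cohort counts of the two hotspot
#'   events (out of `ref_N`).
#' @param ref_N reference cohort size used for marginal probabilities.
#' @param arm_freq_common,arm_freq_rare prior per-arm event frequencies:
#'   the common pair (gain on the first q arm, loss on the second q arm)
#'   versus all other arm events.
#' @param whole_arm_prob probability a planted event spans its whole arm
#'   (otherwise focal with random bounds).
#' @param event_amp mean |log2 ratio| of planted events.
#' @param probes_per_arm inclusive range of probes per arm.
#' @param noise_sd per-probe Gaussian noise SD (log2 ratio).
#' @param jitter_probes boundary jitter (in probes) between the trunk
#'   event copies of two related lesions.
#' @param group_size probes averaged per marker.
#' @param depth_mean mean per-locus sequencing depth for coverage
#'   simulation.
#' @param gc_bias_slope planted linear dependence of log2 coverage ratio
#'   on GC fraction (0 disables).
#' @param seed master RNG seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 20,
                              lesions_per_patient = c(2, 3),
                              clonal_fraction = 0.7,
                              xi = 0.5,
                              burden_mean = 33,
                              burden_size = 5,
                              hyper_prob = 0.06,
                              hyper_burden = 500,
                              catalog_size = 2000,
                              n_genes = 60,
                              hotspot_counts = c(300, 250),
                              ref_N = 1000,
                              arm_freq_common = 0.7,
                              arm_freq_rare = 0.10,
                              whole_arm_prob = 0.5,
                              event_amp = 0.45,
                              probes_per_arm = c(200, 600),
                              noise_sd = 0.15,
                              jitter_probes = 24,
                              group_size = 12,
                              depth_mean = 192,
                              gc_bias_slope = 0,
                              seed = 1L) {
  stopifnot(xi >= 0, xi < 1, clonal_fraction >= 0, clonal_fraction <= 1,
            n_patients >= 1, burden_mean > 0, catalog_size >= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

# Mutation catalog: two hotspot loci in CDH1/PIK3CA-like genes plus a
# power-law tail; reference counts x_i out of ref_N tumors.
sim_catalog <- function(config) {
  k <- config$catalog_size
  genes <- c("CDH1", "PIK3CA",
             sprintf("GENE%03d", seq_len(config$n_genes - 2)))
  gene_of <- c("CDH1", "PIK3CA",
               sample(genes[-(1:2)], k - 2, replace = TRUE))
  # power-law reference counts, capped so marginals stay modest; the
  # expected recurrent load per lesion (sum of marginals) is ~3, the
  # rest of a lesion's burden being never-recurrent loci
  tail_counts <- pmin(stats::rpois(k - 2, 220 * seq_len(k - 2)^-0.9), 30)
  counts <- c(config$hotspot_counts, tail_counts)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, k, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  data.frame(
    chrom = as.character(sample(1:4, k, replace = TRUE)),
    pos = sample(1e7, k),
    ref = ref, alt = alt, gene = gene_of,
    count = counts,
    stringsAsFactors = FALSE
  )
}

catalog_reference <- function(catalog, config, genome) {
  gene_counts <- stats::aggregate(count ~ gene, catalog, sum)
  gene_counts$count <- pmin(gene_counts$count, config$ref_N)
  arm_freqs <- default_arm_priors(genome, config)
  frequency_reference(N = config$ref_N,
                      locus_counts = catalog[c("chrom", "pos", "ref", "alt", "count")],
                      gene_counts = gene_counts,
                      arm_freqs = arm_freqs)
}

# Prior arm-event frequencies: common gain on the first q arm and common
# loss on the second q arm (1q-gain / 16q-loss stand-ins), rare elsewhere.
default_arm_priors <- function(genome, config) {
  arms <- genome$arms$arm
  q_arms <- arms[endsWith(arms, "q")]
  grid <- expand.grid(arm = arms, event = c("gain", "loss"),
                      stringsAsFactors = FALSE)
  grid$freq <- config$arm_freq_rare
  grid$freq[grid$arm == q_arms[1] & grid$event == "gain"] <- config$arm_freq_common
  grid$freq[grid$arm == q_arms[2] & grid$event == "loss"] <- config$arm_freq_common
  grid
}

# Draw a set of arm events (at most one per arm) from the priors.
draw_arm_events <- function(priors, config, n_probes_by_arm) {
  evs <- list()
  for (a in names(n_probes_by_arm)) {
    pg <- priors$freq[priors$arm == a & priors$event == "gain"]
    pl <- priors$freq[priors$arm == a & priors$event == "loss"]
    u <- stats::runif(1)
    ev <- if (u < pg) "gain" else if (u < pg + pl) "loss" else NA
    if (is.na(ev)) next
    np <- n_probes_by_arm[[a]]
    if (stats::runif(1) < config$whole_arm_prob || np < 8) {
      s <- 1L; e <- np
    } else {
      len <- max(4L, round(stats::runif(1, 0.25, 0.75) * np))
      s <- sample(max(1L, np - len + 1L), 1)
      e <- min(np, s + len - 1L)
    }
    amp <- abs(stats::rnorm(1, config$event_amp, 0.08))
    evs[[a]] <- data.frame(arm = a, event = ev, start_probe = s,
                           end_probe = e,
                           amp = if (ev == "gain") amp else -amp,
                           stringsAsFactors = FALSE)
  }
  if (length(evs)) do.call(rbind, evs) else
    data.frame(arm = character(), event = character(),
               start_probe = integer(), end_probe = integer(),
               amp = numeric())
}

# Apply +/- jitter to event boundaries (clonal partner's copy).
jitter_events <- function(events, config, n_probes_by_arm) {
  if (nrow(events) == 0 || config$jitter_probes == 0) return(events)
  for (i in seq_len(nrow(events))) {
    np <- n_probes_by_arm[[events$arm[i]]]
    j <- sample(-config$jitter_probes:config$jitter_probes, 2, replace = TRUE)
    s <- min(max(1L, events$start_probe[i] + j[1]), np)
    e <- min(max(1L, events$end_probe[i] + j[2]), np)
    if (e < s) { tmp <- s; s <- e; e <- tmp }
    events$start_probe[i] <- s
    events$end_probe[i] <- e
  }
  events
}

# Cohort-wide array design: probe positions per arm, shared by every
# lesion (as on a real platform, so marker grids match across patients).
sim_array_design <- function(genome, config) {
  design <- list()
  for (i in seq_len(nrow(genome$arms))) {
    np <- sample_range(config$probes_per_arm[1], config$probes_per_arm[2])
    design[[genome$arms$arm[i]]] <- list(
      chrom = genome$arms$chrom[i],
      pos = sort(sample(genome$arms$start[i]:genome$arms$end[i], np)),
      n = np)
  }
  design
}

# Probe profile for one lesion given its arm events and the array design.
sim_probe_profile <- function(lesion, patient, histology, events,
                              design, genome, config) {
  probes <- list()
  for (a in names(design)) {
    d <- design[[a]]
    x <- stats::rnorm(d$n, 0, config$noise_sd)
    ev <- events[events$arm == a, , drop = FALSE]
    if (nrow(ev) == 1) {
      x[ev$start_probe:ev$end_probe] <- x[ev$start_probe:ev$end_probe] + ev$amp
    }
    probes[[a]] <- data.frame(chrom = d$chrom, pos = d$pos,
                              logratio = x, stringsAsFactors = FALSE)
  }
  probe_profile(lesion, patient, histology, do.call(rbind, probes), genome)
}

# Novel (reference-absent) mutations: globally unique keys at positions
# beyond the catalog range, so they never match between lesions except
# through a shared trunk; their marginal probability is the pseudo-count
# floor, mirroring the vast space of never-recurrent somatic loci.
sim_novel_mutations <- function(k, counter_env, genes) {
  if (k <= 0) return(NULL)
  idx <- counter_env$n + seq_len(k)
  counter_env$n <- counter_env$n + k
  data.frame(chrom = as.character(1 + (idx %% 4)),
             pos = 2e7 + idx, ref = "C", alt = "A",
             gene = sample(genes, k, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Mutation profile for one lesion. Recurrent catalog mutations are
# carried independently with their reference marginal probability (so
# the emitted data are exactly consistent with the frequency reference
# the LR test consumes); the remaining burden is filled with novel
# private loci. Related lesions additionally inherit the patient trunk.
sim_mutation_profile <- function(lesion, patient, histology, burden,
                                 trunk_rows, trunk_rec_idx, catalog, p_cat,
                                 counter_env, config) {
  rec_draw <- which(stats::runif(nrow(catalog)) < p_cat)
  rec_draw <- setdiff(rec_draw, trunk_rec_idx)
  n_trunk <- if (is.null(trunk_rows)) 0L else nrow(trunk_rows)
  # keep the realized burden at its drawn value (the cap almost never
  # binds: the expected recurrent load is far below typical burdens)
  room <- max(0L, burden - n_trunk)
  if (length(rec_draw) > room) rec_draw <- sort(sample(rec_draw, room))
  n_novel <- max(0L, burden - n_trunk - length(rec_draw))
  genes <- unique(catalog$gene)
  rows <- rbind(trunk_rows,
                catalog[rec_draw, c("chrom", "pos", "ref", "alt", "gene")],
                sim_novel_mutations(n_novel, counter_env, genes))
  funcs <- sample(c("missense", "synonymous", "nonsense", "frameshift", "splice"),
                  nrow(rows), replace = TRUE,
                  prob = c(0.55, 0.30, 0.06, 0.06, 0.03))
  mutation_profile(lesion, patient, histology,
                   data.frame(rows,
                              protein_change = NA_character_,
                              func_class = funcs, pop_af = NA_real_,
                              stringsAsFactors = FALSE))
}

#' Simulate a cohort of lesion pairs with known ground truth
#'
#' For each patient, lesions are either clonally related (they share a
#' trunk of mutations amounting to fraction `xi` of each lesion's
#' burden, and carry copies of the same arm events with boundary
#' jitter) or independent (all events drawn separately from the same
#' priors). Probe-level array profiles, mutation tables, and a frequency
#' reference consistent with the catalog are produced; the planted truth
#' is returned alongside.
#'
#' @param config a [simulation_config()].
#' @param mutations,probes logical switches to skip either data type.
#' @return A list of class `synthetic_cohort`: `genome`, `config`,
#'   `lesions` (each with `lesion`, `patient`, `histology`,
#'   `probe_profile`, `mutation_profile`), `ref_freq`, `catalog`,
#'   `truth` (per patient: `related`, `xi`, trunk mutation keys, trunk
#'   events).
#' @export
simulate_cohort <- function(config = simulation_config(),
                            mutations = TRUE, probes = TRUE) {
  set.seed(config$seed)
  genome <- toy_genome()
  catalog <- sim_catalog(config)
  ref_freq <- catalog_reference(catalog, config, genome)
  priors <- ref_freq$arm_freqs
  p_cat <- (catalog$count + ref_freq$alpha) / (config$ref_N + 2 * ref_freq$alpha)
  novel_counter <- new.env()
  novel_counter$n <- 0L
  design <- if (probes) sim_array_design(genome, config) else NULL
  n_probes_by_arm <- if (probes) lapply(design, `[[`, "n") else
    stats::setNames(as.list(rep(300L, nrow(genome$arms))), genome$arms$arm)
  lesions <- list()
  truth <- list()
  for (pid in seq_len(config$n_patients)) {
    patient <- sprintf("P%02d", pid)
    n_les <- sample_range(config$lesions_per_patient[1],
                          config$lesions_per_patient[2])
    related <- stats::runif(1) < config$clonal_fraction
    burdens <- ifelse(
      stats::runif(n_les) < config$hyper_prob,
      config$hyper_burden,
      pmax(1L, stats::rnbinom(n_les, mu = config$burden_mean,
                              size = config$burden_size)))
    trunk_rec_idx <- integer(0)
    trunk_rows <- NULL
    trunk_events <- draw_arm_events(priors, config, n_probes_by_arm)
    if (related && mutations) {
      # ancestral trunk: its recurrent part follows the reference
      # marginals; novel trunk loci fill it to fraction xi of the
      # smallest lesion burden
      t_size <- round(config$xi * min(burdens))
      anc_rec <- which(stats::runif(nrow(catalog)) < p_cat)
      if (length(anc_rec) > t_size) anc_rec <- sort(sample(anc_rec, t_size))
      trunk_rec_idx <- anc_rec
      trunk_rows <- rbind(
        catalog[anc_rec, c("chrom", "pos", "ref", "alt", "gene")],
        sim_novel_mutations(t_size - length(anc_rec), novel_counter,
                            unique(catalog$gene)))
    }
    hists <- c("LCIS", sample(c("LCIS", "ILC", "DCIS", "IDC"), n_les - 1,
                              replace = TRUE))
    for (l in seq_len(n_les)) {
      lesion <- sprintf("%s_L%d", patient, l)
      events <- if (related) {
        jitter_events(trunk_events, config, n_probes_by_arm)
      } else {
        draw_arm_events(priors, config, n_probes_by_arm)
      }
      mp <- if (mutations) {
        sim_mutation_profile(lesion, patient, hists[l], burdens[l],
                             if (related) trunk_rows else NULL,
                             trunk_rec_idx, catalog, p_cat,
                             novel_counter, config)
      } else NULL
      pp <- if (probes) {
        sim_probe_profile(lesion, patient, hists[l], events,
                          design, genome, config)
      } else NULL
      lesions[[lesion]] <- list(lesion = lesion, patient = patient,
                                histology = hists[l],
                                probe_profile = pp, mutation_profile = mp)
    }
    truth[[patient]] <- list(
      patient = patient, related = related, xi = if (related) config$xi else 0,
      trunk_keys = if (related && mutations && !is.null(trunk_rows)) {
        mutation_key(trunk_rows$chrom, trunk_rows$pos,
                     trunk_rows$ref, trunk_rows$alt)
      } else character(0),
      trunk_events = if (related) trunk_events else NULL)
  }
  structure(list(genome = genome, config = config, lesions = lesions,
                 ref_freq = ref_freq, catalog = catalog, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  rel <- sum(vapply(x$truth, `[[`, TRUE, "related"))
  cat(sprintf("<synthetic_cohort> %d lesions, %d patients (%d related); seed %d\n",
              length(x$lesions), length(x$truth), rel, x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort as a self-contained pipeline input directory
#'
#' Emits per-lesion probe and mutation tables, the frequency-reference
#' directory, a YAML manifest, and the ground truth as JSON. The files
#' round-trip exactly through the package readers.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (le in cohort$lesions) {
    entry <- list(lesion = le$lesion, patient = le$patient,
                  histology = le$histology)
    if (!is.null(le$probe_profile)) {
      f <- sprintf("%s_probes.tsv", le$lesion)
      write_probe_profile(le$probe_profile, file.path(dir, f))
      entry$probe_file <- f
    }
    if (!is.null(le$mutation_profile)) {
      f <- sprintf("%s_mutations.tsv", le$lesion)
      write_mutation_table(le$mutation_profile, file.path(dir, f))
      entry$mutation_file <- f
    }
    entries[[length(entries) + 1]] <- entry
  }
  yaml::write_yaml(list(lesions = entries), file.path(dir, "manifest.yaml"))
  write_frequency_reference(cohort$ref_freq, file.path(dir, "reference"))
  jsonlite::write_json(
    lapply(cohort$truth, function(tr) {
      tr["trunk_events"] <- NULL
      tr
    }),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate tumor/normal exome coverage for one lesion
#'
#' Builds capture targets on the toy genome, a GC track (1-kb window GC
#' fraction by convention), Poisson-distributed normal coverage, and
#' tumor coverage scaled by the lesion's planted copy ratio and an
#' optional GC bias, so the exome-derived copy-number path can be tested
#' end to end against the same ground truth as the array path.
#'
#' @param events planted arm events (as in the cohort truth): data frame
#'   `arm`, `event`, `start_probe`, `end_probe`, `amp` — probe bounds are
#'   interpreted as fractions of the arm via the probe count used to
#'   plant them, so pass `frac = TRUE` bounds or whole-arm events for
#'   simplicity.
#' @param genome a [genome_partition()].
#' @param config a [simulation_config()] (`depth_mean`, `gc_bias_slope`).
#' @param targets_per_arm,target_bp number and width of capture target
#'   regions per arm.
#' @param spacing candidate locus spacing within targets (bp).
#' @return List: `targets` (1-based data frame), `gc` (data frame
#'   `chrom`, `pos`, `gc`), `normal`, `tumor` ([coverage_track()]s).
#' @export
simulate_exome_coverage <- function(events, genome, config,
                                    targets_per_arm = 4, target_bp = 5e4,
                                    spacing = 250) {
  targets <- list()
  loci <- list()
  for (i in seq_len(nrow(genome$arms))) {
    a <- genome$arms$arm[i]
    arm_len <- genome$arms$end[i] - genome$arms$start[i] + 1
    starts <- genome$arms$start[i] +
      sort(sample(seq(0, arm_len - target_bp), targets_per_arm))
    for (s in starts) {
      targets[[length(targets) + 1]] <-
        data.frame(chrom = genome$arms$chrom[i], start = s,
                   end = s + target_bp - 1, stringsAsFactors = FALSE)
      pos <- seq(s, s + target_bp - 1, by = spacing)
      loci[[length(loci) + 1]] <-
        data.frame(chrom = genome$arms$chrom[i], pos = pos, arm = a,
                   frac = (pos - genome$arms$start[i]) / arm_len,
                   stringsAsFactors = FALSE)
    }
  }
  targets <- do.call(rbind, targets)
  loci <- do.call(rbind, loci)
  # smooth GC landscape along the genome
  gc <- 0.42 + 0.08 * sin(loci$pos / 7e5) + stats::rnorm(nrow(loci), 0, 0.02)
  gc <- pmin(pmax(gc, 0.2), 0.8)
  copy_lr <- numeric(nrow(loci))
  for (k in seq_len(nrow(events))) {
    a <- events$arm[k]
    np <- max(events$end_probe[k], 1)
    f0 <- (events$start_probe[k] - 1) / np
    f1 <- events$end_probe[k] / np
    sel <- loci$arm == a & loci$frac >= f0 & loci$frac <= f1
    copy_lr[sel] <- copy_lr[sel] + events$amp[k]
  }
  mu_n <- config$depth_mean
  mu_t <- config$depth_mean * 2^(copy_lr + config$gc_bias_slope * (gc - mean(gc)))
  normal <- coverage_track("normal",
                           data.frame(chrom = loci$chrom, pos = loci$pos,
                                      depth = stats::rpois(nrow(loci), mu_n)))
  tumor <- coverage_track("tumor",
                          data.frame(chrom = loci$chrom, pos = loci$pos,
                                     depth = stats::rpois(nrow(loci), mu_t)))
  list(targets = targets,
       gc = data.frame(chrom = loci$chrom, pos = loci$pos, gc = gc,
                       stringsAsFactors = FALSE),
       normal = normal, tumor = tumor)
}
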