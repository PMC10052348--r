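# Synthetic-data generators with known ground truth. Every generator is a
# pure function of its seed and parameters, so each pipeline stage can be
# tested offline against planted structure.

.aa_alphabet <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Generate a tiered protein family
#'
#' Produces a family with planted similarity structure around a seed
#' protein: each tier descends from its own tier ancestor (a mutant of the
#' seed at 70% of the tier's substitution rate), and tier members are
#' mutants of that ancestor at the remaining 30%. Tiers therefore form
#' coherent clades (tight homologs, mid family, distant relatives) whose
#' distance from the seed grows with the tier's rate.
#'
#' @param tier_sizes proteins per tier; the first tier's first member is
#'   the unmutated seed protein, id `"seed"`.
#' @param rates per-tier total substitution rates, strictly increasing,
#'   each in (0, 0.9); the seed itself is emitted unmutated.
#' @param seq_length length of the generated seed sequence (ignored when
#'   `seed_sequence` is given).
#' @param seed_sequence optional amino-acid string to mutate from.
#' @param seed RNG seed.
#' @return list with `sequences` (named character) and `tiers`
#'   (data.frame: id, tier).
#' @export
generate_protein_family <- function(tier_sizes = c(3L, 4L, 5L),
                                    rates = c(0.03, 0.25, 0.65),
                                    seq_length = 200L, seed_sequence = NULL,
                                    seed = 12345L) {
  stopifnot(length(tier_sizes) == length(rates),
            all(diff(rates) > 0), all(rates > 0 & rates < 0.9))
  with_seed(seed, {
    base <- if (is.null(seed_sequence)) {
      paste(sample(.aa_alphabet, seq_length, replace = TRUE), collapse = "")
    } else {
      assert_that(nzchar(seed_sequence), "empty seed sequence")
      toupper(seed_sequence)
    }
    mutate <- function(from, rate) {
      chars <- strsplit(from, "")[[1]]
      hit <- stats::runif(length(chars)) < rate
      chars[hit] <- vapply(chars[hit], function(ch) {
        sample(setdiff(.aa_alphabet, ch), 1L)
      }, "")
      paste(chars, collapse = "")
    }
    seqs <- character(0)
    tiers <- integer(0)
    for (t in seq_along(tier_sizes)) {
      ancestor <- mutate(base, 0.7 * rates[t])
      for (j in seq_len(tier_sizes[t])) {
        id <- if (t == 1L && j == 1L) "seed" else sprintf("t%d_p%d", t, j)
        seqs[id] <- if (t == 1L && j == 1L) base else mutate(ancestor, 0.3 * rates[t])
        tiers <- c(tiers, t)
      }
    }
    list(sequences = seqs,
         tiers = data.frame(id = names(seqs), tier = tiers))
  })
}

# ~30 medicinal-chemistry-flavored fragments; linkers can be chained by
# SMILES concatenation, caps only terminate a molecule.
.fragment_grammar <- list(
  linkers = c("CC", "CCC", "CCN(C)", "CCNC", "CN(C)", "CCO", "CCOC",
              "CC(=O)N", "CC(=O)NC", "CCS", "CC(C)", "CCNCC",
              "c1ccccc1", "c1ccc(cc1)", "c1ccncc1", "c1ccsc1",
              "C1CCNCC1", "C1CCN(CC1)", "C1CCOC1", "C1CCCCC1",
              "c1cnccn1", "C1CCNC1"),
  caps = c("C", "CC", "O", "N", "NC", "OC", "C(F)(F)F", "Cl", "F",
           "C#N", "C(=O)O", "C(C)C")
)

#' Generate a synthetic compound library
#'
#' Samples SMILES from a fragment grammar (secondary-amine-rich linkers,
#' aromatic and saturated rings, small caps), echoing common
#' medicinal-chemistry chemotypes without claiming realism. All outputs
#' are valid, standardizable SMILES; duplicates are allowed and reported.
#'
#' @param n number of compounds.
#' @param grammar list with `linkers` and `caps` fragment vectors.
#' @param seed RNG seed.
#' @return character vector of SMILES with a `"n_duplicated"` attribute.
#' @export
generate_compound_library <- function(n, grammar = .fragment_grammar,
                                      seed = 12345L) {
  stopifnot(is_count(n), n >= 0)
  if (n == 0L) return(structure(character(0), n_duplicated = 0L))
  with_seed(seed, {
    smi <- vapply(seq_len(n), function(i) {
      k <- sample(1:3, 1L)
      paste0(paste(sample(grammar$linkers, k, replace = TRUE), collapse = ""),
             sample(grammar$caps, 1L))
    }, "")
    structure(smi, n_duplicated = sum(duplicated(smi)))
  })
}

#' Generate bioactivities from a known latent model
#'
#' Emulates the statistical structure PCM regression assumes: a sparse
#' linear signal on compound fingerprint bits, shared across the proteins
#' of the tiers listed in `shared_tiers`, plus protein-specific offsets, an
#' optional compound-protein interaction term, and Gaussian noise. Proteins
#' of other tiers carry no feature-linked component at all: their values
#' are pure noise around the protein offset, with an SD of
#' `distant_noise_mult` times the shared tiers' total SD (unrelated
#' targets' activity determinants lie outside the descriptor space, and
#' their assay distributions are broader and more heterogeneous). Pooling their records therefore
#' dilutes what a model can learn -- the structure training-set selection
#' must recover. A fraction of
#' pairs is emitted twice under a lower-priority activity type with an
#' offset value, exercising the unit-ranking and deduplication rules.
#'
#' @param family output of [generate_protein_family()].
#' @param compounds character vector of SMILES.
#' @param n_records number of (compound, protein) pairs to draw.
#' @param shared_tiers tiers whose proteins share the latent compound
#'   signal.
#' @param signal_fraction when `noise_sd` is `NULL`, the noise SD is
#'   calibrated so signal variance / total variance equals this value on
#'   the shared-tier records.
#' @param noise_sd Gaussian noise SD in pChEMBL units (overrides the
#'   calibration).
#' @param interaction_scale SD of the per-protein coefficient on a second
#'   sparse bit pattern (0 disables).
#' @param n_weights number of active fingerprint bits in the latent signal.
#' @param distant_noise_mult SD multiplier for the non-shared tiers'
#'   records, relative to the shared tiers' total SD.
#' @param dup_fraction fraction of pairs duplicated under a lower-priority
#'   activity type.
#' @param year_range publication years drawn uniformly from this range.
#' @param radius,n_bits fingerprint parameters of the latent model.
#' @param seed RNG seed.
#' @return list with `activities` (raw table: compound_id, smiles,
#'   target_id, activity_type, pchembl, year) and `truth` (latent weights,
#'   offsets, noise SD, per-pair expected values).
#' @export
generate_bioactivity <- function(family, compounds, n_records = 2000L,
                                 shared_tiers = c(1L, 2L),
                                 signal_fraction = 0.8, noise_sd = NULL,
                                 interaction_scale = 0.15, n_weights = 40L,
                                 distant_noise_mult = 2,
                                 dup_fraction = 0.1,
                                 year_range = c(1995L, 2020L),
                                 radius = 2L, n_bits = 256L, seed = 12345L) {
  stopifnot(is_count(n_records), n_records >= 1)
  compounds <- unname(compounds)
  fps <- ob_fingerprints(compounds, type = paste0("ECFP", 2L * radius),
                         n_bits = n_bits)
  assert_that(!anyNA(fps), "compound library contains unparseable SMILES")
  prots <- family$tiers$id
  shared <- family$tiers$tier %in% shared_tiers
  with_seed(seed, {
    w <- numeric(n_bits)
    active <- sample.int(n_bits, n_weights)
    w[active] <- stats::rnorm(n_weights, sd = 0.6)
    w2 <- numeric(n_bits)
    w2[sample.int(n_bits, n_weights)] <- stats::rnorm(n_weights, sd = 0.6)
    offsets <- stats::setNames(stats::rnorm(length(prots), sd = 0.15), prots)
    u <- stats::setNames(stats::rnorm(length(prots), sd = interaction_scale), prots)

    grid_n <- length(compounds) * length(prots)
    stopifnot(n_records <= grid_n)
    pick <- sample.int(grid_n, n_records)
    ci <- ((pick - 1L) %% length(compounds)) + 1L
    pi_ <- ((pick - 1L) %/% length(compounds)) + 1L

    sig_c <- as.numeric(fps %*% w)
    sig2_c <- as.numeric(fps %*% w2)
    mu <- 6 + offsets[pi_] +
      ifelse(shared[pi_], sig_c[ci] + u[pi_] * sig2_c[ci], 0)
    if (is.null(noise_sd)) {
      on_sig <- shared[pi_]
      v <- stats::var(sig_c[ci][on_sig] + u[pi_][on_sig] * sig2_c[ci][on_sig])
      noise_sd <- sqrt(v * (1 - signal_fraction) / signal_fraction)
    }
    # distant tiers: broader spread, none of it feature-linked
    far_sd <- distant_noise_mult * sqrt(stats::var(sig_c) + noise_sd^2)
    pchembl <- mu + stats::rnorm(n_records) * ifelse(shared[pi_], noise_sd, far_sd)
    years <- sample(seq(year_range[1], year_range[2]), n_records, replace = TRUE)
    activities <- data.frame(
      compound_id = paste0("c", ci),
      smiles = compounds[ci],
      target_id = prots[pi_],
      activity_type = "Ki",
      pchembl = pchembl,
      year = years)
    n_dup <- round(dup_fraction * n_records)
    if (n_dup > 0L) {
      di <- sample.int(n_records, n_dup)
      dup <- activities[di, ]
      dup$activity_type <- sample(c("IC50", "EC50", "Kd"), n_dup, replace = TRUE)
      dup$pchembl <- dup$pchembl + stats::rnorm(n_dup, sd = 0.5)
      activities <- rbind(activities, dup)
    }
    rownames(activities) <- NULL
    list(activities = activities,
         truth = list(weights = w, weights_interaction = w2, offsets = offsets,
                      interaction_coef = u, noise_sd = noise_sd, far_sd = far_sd,
                      expected = data.frame(compound_id = paste0("c", ci),
                                            target_id = prots[pi_], mu = mu),
                      radius = radius, n_bits = n_bits))
  })
}

#' Generate a synthetic impedance experiment
#'
#' Builds per-well impedance traces whose post-stimulation response
#' amplitude follows the fixed-slope logistic in inhibitor concentration.
#' Each plate carries double-vehicle wells (drift correction),
#' substrate-only wells (0% anchor), saturating reference-inhibitor wells
#' (100% anchor), and duplicate wells per test concentration. Noise is
#' applied to the response amplitude as a percentage of the
#' reference-vehicle span.
#'
#' @param pic50s named numeric vector of true pIC50 values per compound.
#' @param concentrations molar test concentrations.
#' @param n_plates independent experiments (plates).
#' @param wells_per_conc duplicate wells per concentration and plate.
#' @param noise_pct amplitude noise SD as percent of the response span
#'   (0 makes the chain exact).
#' @param t_substrate stimulation time (minutes); traces run from
#'   `t_substrate - 60` to `t_substrate + 35`.
#' @param seed RNG seed.
#' @return list with `traces` (plate, well, time_min, impedance_ohm),
#'   `plate_map` (plate, well, compound, conc_molar, stimulated), and
#'   `truth` (the pIC50s and amplitude parameters).
#' @export
generate_impedance_experiment <- function(pic50s,
                                          concentrations = 10^seq(-11, -5),
                                          n_plates = 3L, wells_per_conc = 2L,
                                          noise_pct = 5, t_substrate = 0,
                                          seed = 12345L) {
  stopifnot(all(concentrations > 0), length(pic50s) >= 1,
            !is.null(names(pic50s)))
  a_vehicle <- 0.15; a_reference <- 0.90; z0 <- 30; tau <- 8
  tgrid <- seq(t_substrate - 60, t_substrate + 35, by = 1)
  bump <- function(t) ifelse(t > t_substrate,
                             ((t - t_substrate) / tau) * exp(1 - (t - t_substrate) / tau), 0)
  baseline <- function(t) pmin(1, 0.0 + (t - (t_substrate - 60)) / 50)
  span <- a_reference - a_vehicle
  with_seed(seed, {
    traces <- list(); map <- list()
    for (pl in seq_len(n_plates)) {
      wid <- 0L
      add_well <- function(compound, conc, stimulated, amplitude) {
        wid <<- wid + 1L
        well <- sprintf("P%d_W%02d", pl, wid)
        ci <- baseline(tgrid) + if (stimulated) amplitude * bump(tgrid) else 0
        traces[[length(traces) + 1L]] <<- data.frame(
          plate = pl, well = well, time_min = tgrid,
          impedance_ohm = z0 + 15 * ci)
        map[[length(map) + 1L]] <<- data.frame(
          plate = pl, well = well, compound = compound,
          conc_molar = conc, stimulated = stimulated)
      }
      noisy <- function(a) a + stats::rnorm(1, sd = noise_pct / 100 * span)
      for (r in seq_len(wells_per_conc)) add_well("vehicle", NA, FALSE, 0)
      for (r in seq_len(wells_per_conc)) add_well("vehicle", NA, TRUE, noisy(a_vehicle))
      for (r in seq_len(wells_per_conc)) add_well("reference", 1e-5, TRUE, noisy(a_reference))
      for (cmp in names(pic50s)) {
        for (conc in concentrations) {
          theta <- 1 / (1 + 10^(-(pic50s[[cmp]] + log10(conc))))
          for (r in seq_len(wells_per_conc)) {
            add_well(cmp, conc, TRUE, noisy(a_vehicle + span * theta))
          }
        }
      }
    }
    list(traces = do.call(rbind, traces), plate_map = do.call(rbind, map),
         truth = list(pic50s = pic50s, a_vehicle = a_vehicle,
                      a_reference = a_reference, noise_pct = noise_pct))
  })
}

#' Fit dose-response curves per plate and summarize
#'
#' Analyzes each plate independently with [tract_analyze()] and reports
#' the per-compound mean pIC50 with its standard error across plates.
#'
#' @param experiment output of [generate_impedance_experiment()] (or any
#'   list with `traces` and `plate_map` carrying a `plate` column).
#' @param t_substrate,window passed to [tract_analyze()].
#' @return data.frame: compound, mean_pic50, sem_pic50, n_plates.
#' @export
tract_summary <- function(experiment, t_substrate = 0, window = 30) {
  plates <- unique(experiment$plate_map$plate)
  per <- list()
  for (pl in plates) {
    res <- tract_analyze(experiment$traces[experiment$traces$plate == pl, ],
                         experiment$plate_map[experiment$plate_map$plate == pl, ],
                         t_substrate = t_substrate, window = window)
    for (cmp in names(res$fits)) {
      per[[length(per) + 1L]] <- data.frame(plate = pl, compound = cmp,
                                            pic50 = res$fits[[cmp]]$pic50)
    }
  }
  per <- do.call(rbind, per)
  out <- do.call(rbind, lapply(split(per, per$compound), function(p) {
    data.frame(compound = p$compound[1], mean_pic50 = mean(p$pic50),
               sem_pic50 = stats::sd(p$pic50) / sqrt(nrow(p)),
               n_plates = nrow(p))
  }))
  rownames(out) <- NULL
  out
}

#' Build the standard synthetic benchmark world
#'
#' The fixed conditions used throughout the package's tests: 12 proteins
#' in 3 similarity tiers, 400 compounds from the fragment grammar, and
#' 2,000 activity records whose compound signal is shared by tiers 1-2
#' only. Optionally writes all inputs (FASTA, activities CSV, deck SMILES,
#' impedance traces CSV, truth JSON) to a directory.
#'
#' @param seed RNG seed; the world is a pure function of it.
#' @param out_dir optional output directory.
#' @return list with `family`, `compounds`, `bioactivity`, `impedance`,
#'   and `sweep_thresholds` (alignment-score cutoffs matched to the
#'   planted tiers).
#' @export
generate_world <- function(seed = 12345L, out_dir = NULL) {
  family <- generate_protein_family(seed = seed)
  compounds <- generate_compound_library(400L, seed = seed + 1L)
  bio <- generate_bioactivity(family, compounds, n_records = 2000L,
                              seed = seed + 2L)
  imp <- generate_impedance_experiment(c(cmpd_a = 7.5), seed = seed + 3L)
  world <- list(family = family, compounds = compounds, bioactivity = bio,
                impedance = imp, sweep_thresholds = c(850, 500, 150))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(Biostrings::AAStringSet(family$sequences),
                                file.path(out_dir, "targets.fa"))
    utils::write.csv(bio$activities, file.path(out_dir, "activities.csv"),
                     row.names = FALSE)
    writeLines(paste(compounds, paste0("c", seq_along(compounds))),
               file.path(out_dir, "deck.smi"))
    utils::write.csv(imp$traces, file.path(out_dir, "traces.csv"), row.names = FALSE)
    utils::write.csv(imp$plate_map, file.path(out_dir, "plate_map.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(noise_sd = bio$truth$noise_sd,
                              pic50s = as.list(imp$truth$pic50s)),
                         file.path(out_dir, "truth.json"), auto_unbox = TRUE)
  }
  world
}
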