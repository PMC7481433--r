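# The package's standard scaled-down end-to-end study on synthetic phantoms.

#' Run the standard phantom end-to-end benchmark
#'
#' Simulates a seeded phantom cohort (default 80 patients: 50 train, 10
#' validation, 20 test) at a given lesion signal separation, trains the slice
#' classifier and the navigation agent, runs the end-to-end loop on the
#' held-out test patients and evaluates concordance. This is the package's
#' reference experiment: the vignette discusses its design and the acceptance
#' script reports its numbers.
#'
#' The classifier is trained with the benchmark configuration returned by
#' [benchmark_train_config()]: the standard geometry (200-pixel crop,
#' 331-pixel input, 4320-dim features) but the Adam optimizer with weight
#' decay and a smaller batch, which from-scratch training of the compact
#' backbone needs; see the methods vignette.
#'
#' @param seed integer seed controlling simulation, training and evaluation.
#' @param n_patients cohort size before splitting.
#' @param signal_separation lesion effect size (default 2, the "easy" end).
#' @param n_boot bootstrap resamples for the concordance report.
#' @return list with `decision_tumor_acc` (fraction of test patients whose
#'   decision slice carries a tumor flag), `patient_acc` (5-way accuracy of
#'   GG-Pre vs GG-RP), `report_pre` and `report_nb` (concordance reports for
#'   the model and the simulated biopsy), `random_walk_tumor_acc` (random
#'   navigation baseline), the merged prediction table and both fitted models.
#' @export
phantom_benchmark <- function(seed, n_patients = 80L, signal_separation = 2,
                              n_boot = 200L) {
  spec <- phantom_spec(n_patients = n_patients,
                       signal_separation = signal_separation, seed = seed)
  cohort <- generate_cohort(spec, split_fractions = c(train = 0.625,
                                                      val = 0.125,
                                                      test = 0.25))
  classifier <- train_slice_classifier(cohort, benchmark_train_config(seed))
  agent_cfg <- dqn_config(input_dim = classifier$config$feature_dim,
                          seed = seed)
  agent <- train_navigation_agent(cohort, classifier, agent_cfg)
  test <- cohort$manifest$split == "test"
  vols <- cohort$volumes[test]
  man <- cohort$manifest[test, ]
  preds <- predict_cohort(vols, classifier, agent)
  m <- merge(preds, man[, c("patient_id", "gg_rp", "gg_nb")],
             by = "patient_id")
  tumor_at <- function(pid, idx) {
    v <- vols[[which(man$patient_id == pid)]]
    isTRUE(v$tumor_flags[idx + 1L])
  }
  decision_tumor <- mapply(tumor_at, m$patient_id, m$decision_index)

  # random-walk baseline: uniform random actions from the same start slice
  rw_tumor <- with_seed(derive_seed(seed, 7777), {
    vapply(seq_along(vols), function(i) {
      v <- vols[[i]]
      n <- length(v$slices)
      pos <- floor(n / 2)
      for (step in 1:4) {
        d <- sample(-3:3, 1)
        if (d == 0) break
        pos <- min(max(pos + d, 0L), n - 1L)
      }
      isTRUE(v$tumor_flags[pos + 1L])
    }, TRUE)
  })

  probs <- as.matrix(m[, c("p1", "p2", "p3", "p4", "p5")])
  report_pre <- suppressWarnings(
    concordance_report(m$gg_rp, m$gg_pre, probs = probs, n_boot = n_boot,
                       seed = derive_seed(seed, 11)))
  report_nb <- suppressWarnings(
    concordance_report(m$gg_rp, m$gg_nb, n_boot = n_boot,
                       seed = derive_seed(seed, 12)))
  list(decision_tumor_acc = mean(decision_tumor),
       patient_acc = mean(m$gg_pre == m$gg_rp),
       random_walk_tumor_acc = mean(rw_tumor),
       report_pre = report_pre, report_nb = report_nb,
       merged = m, classifier = classifier, agent = agent,
       cohort = cohort)
}

#' Benchmark training configuration for the slice classifier
#'
#' The standard interface geometry with a backbone variant suited to training
#' from scratch on a small cohort: the global-average-pooling head plus
#' global intensity quantiles of the input (position-free channel energies
#' carry the texture cue, upper quantiles the lesion-contrast cue, and
#' neither can memorize patient-specific spatial layouts), Adam (learning
#' rate 1e-3, decayed 0.97 per epoch), decoupled weight decay 1e-4, batch 16,
#' Polyak-averaged weights, up to 40 epochs with patience 12. Geometric
#' augmentation is disabled: the pooled channel means are already
#' orientation-insensitive, so random rotations only perturb the intensity
#' statistics.
#'
#' @param seed RNG seed.
#' @return a [train_config()].
#' @export
benchmark_train_config <- function(seed) {
  train_config(batch_size = 16L, lr = 1e-3, optimizer = "adam",
               weight_decay = 1e-4, augment_enabled = FALSE,
               ema_decay = 0.85, head = "gap", input_stats = TRUE,
               channels = c(8, 16, 16, 32),
               max_epochs = 40L, early_stop_patience = 12L, seed = seed)
}
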