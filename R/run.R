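#' Default experiment configuration
#'
#' A single nested list drives the whole simulate / train / evaluate /
#' recode pipeline; every field has a documented default, and a serialized
#' configuration plus the package version fully determines a run.
#'
#' @param out_dir Directory all artifacts are written to.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return Nested configuration list (class `ucd_run_config`).
#' @export
default_run_config <- function(out_dir = "ucdcoder_run", seed = 1L) {
  seed <- as.integer(seed)
  structure(list(
    out_dir = out_dir,
    seed = seed,
    vocab = list(n_chapters = 20L, codes_per_chapter = 10L, seed = seed + 11L),
    sim = list(
      n_per_year = 250L,       # corpus size per calendar year
      val_per_year = 25L,      # per-year exclusion into the validation set
      test_per_year = 25L,     # per-year exclusion into the test set
      model_params = list(),   # overrides for make_cause_model()
      model_seed = seed + 23L,
      data_seed = seed + 37L
    ),
    model = list(
      embed_dim = 32L, conv_channels = c(48L, 64L, 96L),
      pooling = "global_max", use_gender = TRUE, use_row_embedding = TRUE,
      L = 6L, W = 20L, init_seed = seed + 53L
    ),
    opt = list(lr = 1e-3, batch_size = 256L, epochs = 15L, seed = seed + 71L),
    eval = list(B = 1000L, level = 0.95, k = c(1L, 2L), n_bins = 10L,
                seed = seed + 89L),
    recode = list(fixed_year = 2015L, groups = NULL)  # NULL: rule-change targets
  ), class = "ucd_run_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [default_run_config()]; everything else keeps its default.
#'
#' @param path YAML file.
#' @param seed Fallback global seed if the file sets none.
#' @return `ucd_run_config` list.
#' @export
read_run_config <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  base <- default_run_config(seed = user$seed %||% seed)
  structure(utils::modifyList(unclass(base), user), class = "ucd_run_config")
}

config_hash <- function(config) {
  fnv1a32(paste(utils::capture.output(utils::str(unclass(config))),
                collapse = "\n"))
}

run_paths <- function(config) {
  d <- config$out_dir
  list(
    dir = d,
    vocab = file.path(d, "vocabulary.csv"),
    generator = file.path(d, "generator.json"),
    train = file.path(d, "train.csv"),
    val = file.path(d, "val.csv"),
    test = file.path(d, "test.csv"),
    coder = file.path(d, "coder.rds"),
    history = file.path(d, "history.csv"),
    report = file.path(d, "eval_report.json"),
    baseline = file.path(d, "baseline_comparison.json"),
    summary = file.path(d, "eval_summary.txt"),
    recoded = file.path(d, "recoded.csv"),
    trajectory = file.path(d, "trajectory.csv"),
    recode_summary = file.path(d, "recode_summary.json")
  )
}

run_banner <- function(config, stage, quiet) {
  ucd_log("[%s] config hash %s, seed %d", stage, config_hash(config),
          config$seed, quiet = quiet)
}

#' Simulate a corpus and split it into train / validation / test
#'
#' Generates a year-balanced labeled corpus from a seeded synthetic cause
#' model, then mirrors the stratified split protocol: a fixed number of
#' certificates is randomly excluded *from each year* into the validation
#' and test sets (so the year covariate is identically distributed across
#' splits) and the remainder forms the training set. Writes `train.csv`,
#' `val.csv`, `test.csv`, the vocabulary and the generator configuration
#' under `config$out_dir`.
#'
#' @param config A `ucd_run_config`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(config = default_run_config(), quiet = FALSE) {
  paths <- run_paths(config)
  dir.create(paths$dir, showWarnings = FALSE, recursive = TRUE)
  run_banner(config, "simulate", quiet)
  s <- config$sim
  if (s$val_per_year + s$test_per_year >= s$n_per_year) {
    stop("per-year val+test exclusion must be smaller than n_per_year")
  }
  vocab <- make_synthetic_vocabulary(config$vocab$n_chapters,
                                     config$vocab$codes_per_chapter,
                                     config$vocab$seed)
  model <- make_cause_model(vocab, params = s$model_params, seed = s$model_seed)
  corpus <- generate_corpus(model, s$n_per_year, seed = s$data_seed)
  years <- vapply(corpus, `[[`, 0L, "year")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(s$data_seed + 1L)
  val_idx <- integer(0); test_idx <- integer(0)
  for (y in unique(years)) {
    iy <- which(years == y)
    ex <- sample(iy, s$val_per_year + s$test_per_year)
    val_idx <- c(val_idx, ex[seq_len(s$val_per_year)])
    test_idx <- c(test_idx, ex[-seq_len(s$val_per_year)])
  }
  train_idx <- setdiff(seq_along(corpus), c(val_idx, test_idx))

  write_code_list(vocab, paths$vocab)
  save_cause_model_config(model, vocab_spec = list(
    n_chapters = config$vocab$n_chapters,
    codes_per_chapter = config$vocab$codes_per_chapter,
    seed = config$vocab$seed), paths$generator)
  write_certificates(corpus[train_idx], paths$train)
  write_certificates(corpus[val_idx], paths$val)
  write_certificates(corpus[test_idx], paths$test)
  ucd_log("wrote %d train / %d val / %d test certificates to %s",
          length(train_idx), length(val_idx), length(test_idx), paths$dir,
          quiet = quiet)
  invisible(paths)
}

#' Train a coder on a simulated corpus
#'
#' Reads the train/validation sets written by [run_simulate()], trains the
#' convolutional coder, and writes the checkpoint (`coder.rds`) and the
#' per-epoch history (`history.csv`, with the validation-selected epoch
#' flagged).
#'
#' @inheritParams run_simulate
#' @export
run_train <- function(config = default_run_config(), quiet = FALSE) {
  paths <- run_paths(config)
  for (f in c(paths$train, paths$val, paths$vocab)) {
    if (!file.exists(f)) stop(sprintf("missing input '%s'; run run_simulate() first", f))
  }
  run_banner(config, "train", quiet)
  vocab <- read_code_list(paths$vocab)
  train <- read_certificates(paths$train)
  val <- read_certificates(paths$val)
  m <- config$model
  cfg <- model_config(vocab, embed_dim = m$embed_dim,
                      conv_channels = m$conv_channels, pooling = m$pooling,
                      use_gender = m$use_gender,
                      use_row_embedding = m$use_row_embedding,
                      L = m$L, W = m$W, seed = m$init_seed)
  coder <- build_model(cfg, vocab)
  coder <- train_coder(coder, train, val, vocab, opt_params = config$opt,
                       quiet = quiet)
  save_coder(coder, paths$coder)
  hist <- coder$history
  hist$selected <- hist$val_accuracy == max(hist$val_accuracy)
  utils::write.csv(hist, paths$history, row.names = FALSE)
  ucd_log("best validation accuracy %.4f (epoch %d)", max(hist$val_accuracy),
          which.max(hist$val_accuracy), quiet = quiet)
  invisible(paths)
}

#' Evaluate a trained coder against the rule-based baseline
#'
#' Produces the full evaluation report on the test set and the reject-aware
#' baseline comparison, the baseline being the deterministic oracle (with
#' its reject rule active) run on the identical certificates with the same
#' explanatory variables.
#'
#' @inheritParams run_simulate
#' @export
run_evaluate <- function(config = default_run_config(), quiet = FALSE) {
  paths <- run_paths(config)
  for (f in c(paths$coder, paths$test, paths$vocab, paths$generator)) {
    if (!file.exists(f)) stop(sprintf("missing input '%s'", f))
  }
  run_banner(config, "evaluate", quiet)
  vocab <- read_code_list(paths$vocab)
  coder <- load_coder(paths$coder)
  test <- read_certificates(paths$test)
  model <- restore_cause_model(paths$generator)
  e <- config$eval
  report <- evaluate_coder(coder, test, vocab, B = e$B, level = e$level,
                           k = e$k, n_bins = e$n_bins, seed = e$seed)
  baseline <- compare_with_baseline(
    report$preds, lapply(test, oracle_code, model = model), report$golds)
  write_eval_report(report, paths$report)
  jsonlite::write_json(unclass(baseline), paths$baseline, auto_unbox = TRUE,
                       digits = NA)
  writeLines(c(
    sprintf("config hash: %s", config_hash(config)),
    utils::capture.output(print(report)),
    utils::capture.output(print(baseline))
  ), paths$summary)
  ucd_log("test accuracy %.4f (baseline overall %.4f / nonrejected %.4f)",
          report$accuracy, baseline$overall_accuracy,
          baseline$nonrejected_accuracy, quiet = quiet)
  invisible(list(report = report, baseline = baseline, paths = paths))
}

#' Harmonized recoding of the whole corpus
#'
#' Recodes every simulated certificate with the year of coding fixed
#' (default 2015), counts cause-group deaths per year for the original and
#' the recoded codings, and writes the recoded certificates, the tidy
#' trajectory table and the jump statistics. By default the cause groups are
#' the generator's year-rule-change target codes -- the groups whose
#' original trajectory carries the coding-rule discontinuity.
#'
#' @inheritParams run_simulate
#' @export
run_recode <- function(config = default_run_config(), quiet = FALSE) {
  paths <- run_paths(config)
  for (f in c(paths$coder, paths$train, paths$val, paths$test, paths$vocab,
              paths$generator)) {
    if (!file.exists(f)) stop(sprintf("missing input '%s'", f))
  }
  run_banner(config, "recode", quiet)
  vocab <- read_code_list(paths$vocab)
  coder <- load_coder(paths$coder)
  corpus <- c(read_certificates(paths$train), read_certificates(paths$val),
              read_certificates(paths$test))
  years <- vapply(corpus, `[[`, 0L, "year")
  golds <- vapply(corpus, `[[`, "", "gold_ucd")

  groups <- config$recode$groups
  if (is.null(groups)) {
    model <- restore_cause_model(paths$generator)
    groups <- list(cause_group("rule_change_targets",
                               unname(model$rule_change$map)))
  }
  fixed_year <- config$recode$fixed_year
  recoded <- recode_certificates(coder, corpus, vocab, fixed_year)

  year_range <- seq(min(years), max(years))
  ts_orig <- count_by_group(golds, years, groups, year_range, "original")
  ts_reco <- count_by_group(recoded, years, groups, year_range, "recoded")
  comp <- trajectory_comparison(ts_orig, ts_reco)

  out <- corpus
  for (i in seq_along(out)) out[[i]]$gold_ucd <- recoded[i]
  write_certificates(out, paths$recoded)
  rec_df <- utils::read.csv(paths$recoded, colClasses = "character")
  rec_df$provenance <- sprintf("model@%d", fixed_year)
  utils::write.csv(rec_df, paths$recoded, row.names = FALSE)
  traj <- rbind(as.data.frame(ts_orig), as.data.frame(ts_reco))
  utils::write.csv(traj, paths$trajectory, row.names = FALSE)
  jsonlite::write_json(
    list(fixed_year = fixed_year, jump_original = comp$jump_original,
         jump_recoded = comp$jump_recoded,
         yoy_original = as.list(comp$yoy_original),
         yoy_recoded = as.list(comp$yoy_recoded)),
    paths$recode_summary, auto_unbox = TRUE, digits = NA)
  ucd_log("max year-over-year jump: original %g, recoded-at-%d %g",
          comp$jump_original, fixed_year, comp$jump_recoded, quiet = quiet)
  invisible(list(original = ts_orig, recoded = ts_reco, comparison = comp,
                 paths = paths))
}
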