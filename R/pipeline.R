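#' Default pipeline configuration
#'
#' All knobs of the end-to-end run in one list: cohort sizes, lexicon
#' shape, embedding dimensions, block-model settings, MCMC schedule and
#' alpha conventions. `n_per_group = NULL` uses the per-profile sizes.
#'
#' @param ... named overrides of the defaults
#' @export
fluency_config <- function(...) {
  cfg <- list(
    seed = 1,
    n_per_group = NULL,
    lexicon_size = 1000, zipf_s = 1, rare_gap = 4,
    stay_prob = 0.4,
    embed_d_graph = 2048, embed_d_predict = 1024, project_k = 256,
    sbm_Q = 8, sbm_sweeps = 20, sbm_max_blocks = NULL,
    mcmc = c(burn = 2000, samples = 2000, thin = 2),
    family_alpha = 0.05, community_divisor = 40,
    style = NULL,
    out_dir = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> score -> embed -> graph -> communities -> predictive
#' models -> group statistics, writing every intermediate artifact when
#' `config$out_dir` is set and returning a structured report. The
#' configured seed drives every stochastic stage.
#'
#' @param config a [fluency_config()] list
#' @return report list with elements `scorecards_summary`,
#'   `community_table`, `model_comparison`, `group_stats`, `timings`
#' @export
run_pipeline <- function(config = fluency_config()) {
  t_all <- proc.time()[["elapsed"]]
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  lexicon <- stage("lexicon", make_lexicon(config$lexicon_size,
                                           config$zipf_s, config$seed,
                                           config$rare_gap))
  profiles <- make_default_profiles()
  cohort <- stage("simulate", simulate_cohort(
    profiles, lexicon, seed = config$seed,
    n_per_group = config$n_per_group, stay_prob = config$stay_prob,
    style = config$style))
  scored <- stage("score", score_cohort(cohort$transcripts, lexicon))
  if (!is.null(out_dir)) {
    write_cohort(cohort, out_dir)
    write_lexicon(lexicon, file.path(out_dir, "lexicon.tsv"))
    utils::write.table(scored, file.path(out_dir, "scorecards.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  G <- stage("graph", build_similarity_graph(cohort, lexicon,
                                             d = config$embed_d_graph,
                                             seed = config$seed))
  partition <- stage("communities", fit_sbm(
    G, max_blocks = config$sbm_max_blocks, n_sweeps = config$sbm_sweeps,
    seed = config$seed, Q = config$sbm_Q))
  profiles_comm <- profile_communities(partition, cohort$participants,
                                       cohort$transcripts, scored)
  contrasts_comm <- community_contrasts(partition, cohort$participants,
                                        scored,
                                        alpha_family = config$family_alpha,
                                        divisor = config$community_divisor)
  if (!is.null(out_dir)) {
    utils::write.table(
      data.frame(participant_id = names(partition$assignment),
                 block = partition$assignment),
      file.path(out_dir, "partition.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(profiles_comm,
                         file.path(out_dir, "community_profiles.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  model_cmp <- stage("predict", {
    E_pred <- embed_sequences(cohort$transcripts,
                              d = config$embed_d_predict,
                              seed = config$seed)
    proj <- random_project(E_pred, k = config$project_k,
                           seed = config$seed)
    feats <- merge(cohort$participants, scored, by = "participant_id")
    feats <- feats[match(rownames(E_pred), feats$participant_id), ]
    compare_models(feats, proj,
                   specs = default_model_specs(mcmc = config$mcmc),
                   seed = config$seed)
  })

  stats_tab <- stage("stats", {
    feats <- merge(cohort$participants, scored, by = "participant_id")
    covs <- feats[, c("age", "nart")]
    lapply(stats::setNames(nm = c("correct_words", "pct_rulebreak",
                                  "pct_lowfreq")), function(v) {
      a <- ancova(feats[[v]], feats$group, covs)
      list(F = a$F, df_between = a$df_between, df_within = a$df_within,
           p = a$p, partial_eta_sq = a$partial_eta_sq)
    })
  })

  report <- list(
    schema_version = "1.0",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed,
    n_participants = nrow(cohort$participants),
    lowfreq_threshold = attr(scored, "lowfreq_threshold"),
    scorecards_summary = scorecard_group_summary(scored,
                                                 cohort$participants),
    community_table = list(
      n_blocks = partition$n_blocks,
      description_length = partition$description_length,
      profiles = profiles_comm,
      contrasts = contrasts_comm
    ),
    model_comparison = model_cmp,
    group_stats = stats_tab,
    timings = as.list(timings),
    total_elapsed = round(proc.time()[["elapsed"]] - t_all, 2)
  )
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

#' Group-level summary of scorecards
#'
#' Mean (SD) of the principal scorecard metrics per group; the synthetic
#' analogue of a cohort characteristics table.
#' @param scored output of [score_cohort()]
#' @param participants cohort metadata
#' @export
scorecard_group_summary <- function(scored, participants) {
  d <- merge(participants, scored, by = "participant_id")
  vars <- c("correct_words", "pct_rulebreak", "pct_inappropriate",
            "pct_proper_noun", "pct_permutation", "pct_perseveration",
            "pct_lowfreq", "mean_cluster_size", "relative_switches")
  out <- lapply(split(d, d$group), function(g) {
    c(list(n = nrow(g)),
      stats::setNames(lapply(vars, function(v) {
        x <- g[[v]][is.finite(g[[v]])]
        list(mean = mean(x), sd = stats::sd(x))
      }), vars))
  })
  out
}
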