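#' Default pipeline configuration
#'
#' All tunables of the end-to-end analysis in one list. Paths may point at
#' wide per-feature TSVs plus a cohort TSV, or `simulate` may carry a
#' [cohort_spec()] to generate inputs on the fly.
#'
#' @param ... overrides of the defaults.
#' @return list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    feature_paths = NULL,        # named vector of wide TSVs
    cohort_path = NULL,          # covariate TSV
    simulate = NULL,             # cohort_spec, used when paths are NULL
    transform = "abs",           # weight transform for graph measures
    modularity_rounds = 100L,
    seed = 1L,
    tails = "two",               # a-priori default; "one" = replication mode
    direction = "observed",
    alpha = 0.05,
    fdr_method = "BH",
    hub_threshold = 0.30,
    mmse_zone = c(28, 30),
    vote = "majority",
    outlier_rule = "iqr",
    out_dir = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  stopifnot(cfg$alpha > 0, cfg$alpha < 1,
            cfg$hub_threshold >= 0, cfg$hub_threshold <= 1,
            cfg$mmse_zone[1] <= cfg$mmse_zone[2])
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages, in order: ingest or simulate the morphometry tensor; z-score;
#' build one network per subject; per-subject graph metrics; edge-wise
#' group comparison with FDR and change classification; group-consensus
#' hubs; MMSE-plus-network screening; TSV/JSON/viewer exports. Every
#' artifact is written under `cfg$out_dir` together with a provenance
#' block (config echo, seed, package version, config hash).
#'
#' @param cfg a [default_config()] list.
#' @return Invisibly, a list with the in-memory results (`tensor`,
#'   `cohort`, `networks`, `metrics`, `edge_comparison`, `hubs`,
#'   `screening`, `summary`) and `out_dir`.
#' @export
run_pipeline <- function(cfg = default_config()) {
  stopifnot(inherits(cfg, "run_config"))
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("morphnet_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  atlas <- dk_atlas()

  # --- ingest or simulate -------------------------------------------------
  if (!is.null(cfg$feature_paths)) {
    tensor <- read_feature_tables(cfg$feature_paths, atlas)
    cohort <- read_cohort_table(cfg$cohort_path)
  } else if (!is.null(cfg$simulate)) {
    spec <- cfg$simulate
    if (is.null(spec$seed)) spec$seed <- cfg$seed
    sim <- generate_cohort(spec)
    tensor <- sim$tensor
    cohort <- sim$cohort
  } else {
    stop("config must provide feature_paths or a simulate spec")
  }
  cohort <- cohort[match(tensor$subjects, cohort$subject), , drop = FALSE]
  if (anyNA(cohort$subject)) {
    stop("cohort table does not cover all subjects in the feature tables")
  }

  # --- networks and per-subject metrics ----------------------------------
  z <- zscore_features(tensor)
  networks <- lapply(tensor$subjects, function(s) build_network(z, s))
  names(networks) <- tensor$subjects
  metrics <- lapply(seq_along(networks), function(i)
    compute_all_metrics(networks[[i]], transform = cfg$transform,
                        rounds = cfg$modularity_rounds,
                        seed = cfg$seed + i))
  names(metrics) <- tensor$subjects
  metrics_df <- data.frame(
    subject = tensor$subjects,
    group = cohort$group,
    mmse = cohort$mmse,
    e_global = vapply(metrics, `[[`, numeric(1), "e_global"),
    q = vapply(metrics, `[[`, numeric(1), "q"),
    m_e_local = vapply(metrics, `[[`, numeric(1), "m_e_local"),
    m_bc = vapply(metrics, `[[`, numeric(1), "m_bc"),
    stringsAsFactors = FALSE)

  # --- group statistics ---------------------------------------------------
  is_nc <- cohort$group == "NC"
  cmp <- edgewise_comparison(networks[is_nc], networks[!is_nc],
                             alpha = cfg$alpha, tails = cfg$tails,
                             direction = cfg$direction,
                             outlier_rule = cfg$outlier_rule,
                             fdr_method = cfg$fdr_method)

  hub_tab <- list()
  nbc_mats <- list()
  for (g in c("NC", "AD")) {
    sel <- cohort$group == g
    hub_sets <- lapply(metrics[sel], `[[`, "hubs")
    nbc <- t(vapply(metrics[sel], `[[`, numeric(68), "n_bc"))
    bc <- t(vapply(metrics[sel], `[[`, numeric(68), "bc"))
    hub_tab[[g]] <- consensus_hubs(hub_sets, atlas$region,
                                   threshold = cfg$hub_threshold,
                                   nbc_matrix = nbc, bc_matrix = bc)
    nbc_mats[[g]] <- nbc
  }

  screening <- mmse_screen(metrics_df, zone = cfg$mmse_zone,
                           vote = cfg$vote)

  # --- exports ------------------------------------------------------------
  wt <- function(x, f) {
    utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(metrics_df, "metrics.tsv")
  nodal <- do.call(rbind, lapply(names(metrics), function(s) {
    m <- metrics[[s]]
    data.frame(subject = s, region = atlas$region, e_local = m$e_local,
               bc = m$bc, n_bc = m$n_bc,
               is_hub = atlas$region %in% m$hubs, stringsAsFactors = FALSE)
  }))
  wt(nodal, "nodal_metrics.tsv")
  wt(cmp, "edge_comparison.tsv")
  wt(hub_tab$NC, "consensus_hubs_nc.tsv")
  wt(hub_tab$AD, "consensus_hubs_ad.tsv")
  wt(as.data.frame(screening), "screening.tsv")
  for (g in c("NC", "AD")) {
    sel <- cohort$group == g
    mean_r <- Reduce(`+`, lapply(networks[sel], `[[`, "r")) / sum(sel)
    mean_conn <- structure(list(r = mean_r, subject = paste0("mean_", g),
                                regions = atlas$region),
                           class = "conn_matrix")
    write_brainnet(mean_conn, file.path(out_dir, paste0("group_", g)),
                   n_bc = colMeans(nbc_mats[[g]]),
                   transform = cfg$transform)
  }

  cfg_echo <- cfg
  cfg_echo$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate)
  summary <- list(
    package_version = as.character(utils::packageVersion("morphnet")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    n_subjects = nrow(cohort),
    n_edges = nrow(cmp),
    n_significant = sum(cmp$significant),
    significant_by_class = as.list(table(
      cmp$change_class[cmp$significant])),
    hubs_nc = hub_tab$NC$region[hub_tab$NC$is_hub],
    hubs_ad = hub_tab$AD$region[hub_tab$AD$is_hub],
    screening_confusion = if (!anyNA(screening$predicted))
      as.list(table(truth = cohort$group,
                    predicted = screening$predicted))
    else NULL,
    config = cfg_echo)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

  invisible(list(tensor = tensor, cohort = cohort, networks = networks,
                 metrics = metrics, metrics_df = metrics_df,
                 edge_comparison = cmp, hubs = hub_tab,
                 screening = screening, summary = summary,
                 out_dir = out_dir))
}

# stable short hash of the configuration (djb2 over its serialization)
config_hash <- function(cfg) {
  bytes <- serialize(lapply(unclass(cfg), function(x)
    if (is.list(x)) unclass(x) else x), NULL, version = 2)
  h <- 5381
  for (b in as.integer(bytes)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
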