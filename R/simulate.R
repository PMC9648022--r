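# Synthetic-data generators emulating the study design: several
# independent expression datasets sharing gene symbols, with planted
# stepwise, direction-inconsistent and null genes and inflated SCC
# heterogeneity; interaction networks with planted hubs; paired IHC marker
# calls at specified operating points with copula-controlled dependence;
# right-censored survival cohorts whose hazard depends on a marker.

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: three discovery datasets,
#' eight samples per stage, a +1 log2 per-stage effect for stepwise genes
#' over a 0.5-SD noise floor, 1.5x noise inflation at the carcinoma stage,
#' marker operating points (sensitivity 0.882, specificity 0.901) at the
#' diagnostic cohort's sizes (68 diseased / 101 controls), and a
#' three-cohort-scale survival generator.
#'
#' @param seed RNG seed.
#' @param n_datasets number of expression datasets (default 3).
#' @param genes_total genes per dataset (default 500).
#' @param n_per_stage samples per stage per dataset (default 8).
#' @param n_stepwise planted monotone genes, split half up / half down
#'   (default 50).
#' @param delta per-stage log2 effect of stepwise genes (default 1).
#' @param n_inconsistent genes whose direction flips between datasets
#'   (default 20).
#' @param noise_sd within-stage SD on the log2 scale (default 0.5).
#' @param gene_baseline_sd SD of per-gene baseline log2 expression around
#'   `base_mean` (default 2): genes differ in absolute expression, giving
#'   the high between-sample correlations typical of array profiles.
#' @param scc_inflation multiplicative SD inflation for SCC samples
#'   (default 1.5).
#' @param base_mean baseline log2 expression (default 8).
#' @param network_size,n_hubs,background_p,hub_wiring network generator:
#'   node count, planted hubs, background edge probability, fraction of
#'   nodes each hub wires to.
#' @param ihc_n_diseased,ihc_n_controls,ihc_sens,ihc_spec,ihc_dependence
#'   IHC generator: cohort sizes, per-marker operating points (recycled
#'   over markers), and the shared-latent loading in `[0, 1]` controlling
#'   inter-marker dependence.
#' @param surv_n,surv_log_hr,surv_baseline_hazard,surv_censor_rate
#'   survival generator: cohort size, marker log hazard ratio, baseline
#'   hazard per month, and target pre-horizon censoring rate.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_datasets = 3, genes_total = 500, n_per_stage = 8,
                       n_stepwise = 50, delta = 1, n_inconsistent = 20,
                       noise_sd = 0.5, gene_baseline_sd = 2,
                       scc_inflation = 1.5, base_mean = 8,
                       network_size = 60, n_hubs = 4, background_p = 0.05,
                       hub_wiring = 0.4,
                       ihc_n_diseased = 68, ihc_n_controls = 101,
                       ihc_sens = 0.882, ihc_spec = 0.901,
                       ihc_dependence = 0.5,
                       surv_n = 252, surv_log_hr = -0.7,
                       surv_baseline_hazard = 0.01, surv_censor_rate = 0.2) {
  cfg <- as.list(environment())
  stopifnot(n_datasets >= 1, genes_total >= n_stepwise + n_inconsistent,
            n_per_stage >= 2, noise_sd > 0, scc_inflation > 0,
            n_hubs < network_size, background_p >= 0, background_p <= 1,
            hub_wiring > 0, hub_wiring <= 1,
            ihc_sens > 0, ihc_sens < 1, ihc_spec > 0, ihc_spec < 1,
            ihc_dependence >= 0, ihc_dependence <= 1,
            surv_censor_rate >= 0, surv_censor_rate < 1)
  structure(cfg, class = "sim_config")
}

#' Generate the expression datasets with planted truth
#'
#' Per dataset: stepwise genes have stage means `base_mean + k * delta`
#' (`k` = stage code 0..3; down-genes use `-delta`) in every dataset;
#' inconsistent genes use `+delta` in odd-numbered datasets and `-delta` in
#' even ones; the remaining genes are null.  SCC samples draw noise with SD
#' `noise_sd * scc_inflation`, reproducing the higher within-carcinoma
#' heterogeneity.  Gene symbols are shared across datasets.
#'
#' @param cfg a [sim_config()].
#' @return list with `datasets` (list of [expression_dataset()]) and
#'   `truth` (data.frame: gene, role in
#'   stepwise_up/stepwise_down/inconsistent/null).
#' @export
gen_expression_datasets <- function(cfg) {
  set.seed(cfg$seed)
  n_up <- ceiling(cfg$n_stepwise / 2)
  n_down <- cfg$n_stepwise - n_up
  n_null <- cfg$genes_total - cfg$n_stepwise - cfg$n_inconsistent
  genes <- sprintf("G%04d", seq_len(cfg$genes_total))
  role <- rep(c("stepwise_up", "stepwise_down", "inconsistent", "null"),
              c(n_up, n_down, cfg$n_inconsistent, n_null))
  stage <- rep(0:3, each = cfg$n_per_stage)
  sds <- ifelse(stage == 3, cfg$noise_sd * cfg$scc_inflation, cfg$noise_sd)
  baseline <- cfg$base_mean + rnorm(cfg$genes_total, 0, cfg$gene_baseline_sd)
  datasets <- lapply(seq_len(cfg$n_datasets), function(d) {
    sign_d <- if (d %% 2 == 1) 1 else -1
    per_stage <- matrix(rep(stage, cfg$genes_total), nrow = cfg$genes_total,
                        byrow = TRUE)
    slope <- ifelse(role == "stepwise_up", cfg$delta,
             ifelse(role == "stepwise_down", -cfg$delta,
             ifelse(role == "inconsistent", sign_d * cfg$delta, 0)))
    mu <- baseline + slope * per_stage
    noise <- matrix(rnorm(length(mu), 0, rep(sds, each = cfg$genes_total)),
                    nrow = cfg$genes_total)
    values <- mu + noise
    rownames(values) <- genes
    colnames(values) <- sprintf("D%d_S%02d", d, seq_along(stage))
    expression_dataset(sprintf("sim%d", d), values, stage)
  })
  list(datasets = datasets, truth = data.frame(gene = genes, role = role))
}

#' Generate an interaction network with planted hubs
#'
#' Erdos-Renyi background at probability `background_p` plus `n_hubs`
#' planted hub nodes, each wired to a random `hub_wiring` fraction of the
#' other nodes.
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return list with `graph` (igraph) and `hubs` (character names of the
#'   planted hubs).
#' @export
gen_network <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  n <- cfg$network_size
  nodes <- sprintf("N%03d", seq_len(n))
  hubs <- nodes[seq_len(cfg$n_hubs)]
  pairs <- combn(n, 2)
  keep <- runif(ncol(pairs)) < cfg$background_p
  edges <- pairs[, keep, drop = FALSE]
  for (h in seq_len(cfg$n_hubs)) {
    others <- setdiff(seq_len(n), h)
    tgt <- sample(others, round(cfg$hub_wiring * length(others)))
    edges <- cbind(edges, rbind(pmin(h, tgt), pmax(h, tgt)))
  }
  el <- unique(t(edges))
  g <- igraph::graph_from_edgelist(
    cbind(nodes[el[, 1]], nodes[el[, 2]]), directed = FALSE)
  g <- igraph::simplify(g)
  missing <- setdiff(nodes, igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing),
                                                 name = missing)
  list(graph = g, hubs = hubs)
}

#' Generate a paired IHC marker-call cohort
#'
#' Sections get a gold-standard stage (controls: Normal/CIN1, diseased:
#' CIN2/CIN3); each marker's binary call is drawn at the marker's
#' sensitivity (diseased) or specificity (controls) through a Gaussian
#' copula: marker-specific latents share a common factor with loading
#' `ihc_dependence`, so 0 gives conditionally independent calls and 1
#' identical calls (for equal operating points).  Raw scores (layer,
#' intensity, percent positive, H-score) are generated consistently with
#' each call.
#'
#' @param cfg a [sim_config()].
#' @param markers character vector of marker names (default two markers).
#' @param seed optional override of `cfg$seed`.
#' @return list with `table` (data.frame: section_id, gold_stage,
#'   gold_substage, truth, and per-marker call/score columns) and `truth`
#'   (logical diseased indicator).
#' @export
gen_ihc_cohort <- function(cfg, markers = c("markerA", "markerB"),
                           seed = cfg$seed) {
  set.seed(seed)
  n1 <- cfg$ihc_n_diseased; n0 <- cfg$ihc_n_controls
  n <- n1 + n0
  diseased <- rep(c(TRUE, FALSE), c(n1, n0))
  substage <- c(sample(c("CIN2", "CIN3"), n1, replace = TRUE),
                sample(c("Normal", "CIN1"), n0, replace = TRUE))
  gold <- parse_stage_label(substage)
  sens <- rep_len(cfg$ihc_sens, length(markers))
  spec <- rep_len(cfg$ihc_spec, length(markers))
  rho <- cfg$ihc_dependence
  z_shared <- rnorm(n)
  tab <- data.frame(section_id = sprintf("S%03d", seq_len(n)),
                    gold_substage = substage,
                    gold_stage = gold, truth = diseased)
  for (j in seq_along(markers)) {
    z <- rho * z_shared + sqrt(1 - rho^2) * rnorm(n)
    u <- pnorm(z)
    # diseased: positive with prob sens; control: positive with prob 1-spec
    p_pos <- ifelse(diseased, sens[j], 1 - spec[j])
    pos <- u < p_pos
    call <- ifelse(pos, "positive", "negative")
    layer <- ifelse(pos, sample(2:3, n, TRUE), sample(0:1, n, TRUE))
    intensity <- ifelse(pos, sample(2:3, n, TRUE), sample(0:1, n, TRUE))
    pct_pos <- ifelse(pos, runif(n, 11, 100), runif(n, 0, 10))
    p3 <- pmin(pct_pos, ifelse(pos, pct_pos * runif(n, 0.3, 0.8), 0))
    p2 <- (pct_pos - p3) * runif(n, 0.3, 0.9)
    p1 <- pct_pos - p3 - p2
    hs <- hscore(p1, p2, p3)
    cols <- data.frame(call, layer, intensity,
                       percent_positive = pct_pos, hscore = hs)
    names(cols) <- paste(markers[j], names(cols), sep = "_")
    tab <- cbind(tab, cols)
  }
  list(table = tab, truth = diseased)
}

#' Generate a right-censored survival cohort
#'
#' Exponential event times with hazard
#' `surv_baseline_hazard * exp(X beta)`, where `X` contains a dichotomous
#' marker (log HR = `surv_log_hr`) and clinical covariates (age, FIGO
#' stage, grade, each with a small effect); independent uniform censoring
#' calibrated to the target pre-horizon rate, then the 5-year
#' administrative horizon.
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return list with `cohort` (data.frame: patient_id, time_months, event,
#'   age, figo_stage, grade, marker_high, marker_value) and `truth`
#'   (the true coefficient vector).
#' @export
gen_survival_cohort <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  n <- cfg$surv_n
  marker_high <- rbinom(n, 1, 0.5)
  age <- round(rnorm(n, 50, 10))
  figo <- sample(1:4, n, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  grade <- sample(1:3, n, TRUE)
  beta <- c(marker_high = cfg$surv_log_hr, age = 0.01, figo_stage = 0.2,
            grade = 0.1)
  lp <- cbind(marker_high, age - 50, figo - 1, grade - 1) %*% beta
  hazard <- cfg$surv_baseline_hazard * exp(as.vector(lp))
  t_event <- rexp(n, hazard)
  if (cfg$surv_censor_rate > 0) {
    # uniform censoring on (0, cmax): P(C < T | h) = (1 - exp(-h cmax)) /
    # (h cmax); calibrate cmax so the mean over subjects hits the target
    cens_frac <- function(cm) mean((1 - exp(-hazard * cm)) / (hazard * cm))
    cmax <- stats::uniroot(function(cm) cens_frac(cm) - cfg$surv_censor_rate,
                           c(1e-6, 1e6))$root
    t_cens <- runif(n, 0, cmax)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  cohort <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                       time_months = time, event = event,
                       age = age, figo_stage = figo, grade = grade,
                       marker_high = marker_high,
                       marker_value = marker_high * 100 + runif(n, 0, 50))
  cohort <- apply_censor_rule(cohort, 60)
  list(cohort = cohort, truth = beta)
}

#' Write a complete synthetic input bundle
#'
#' Emits everything the pipeline consumes into a directory: per-dataset
#' expression and metadata TSVs, a gene-set GMT (cytoband-like blocks of
#' the simulated gene symbols), a network edge list, IHC and survival CSVs,
#' and a JSON truth summary.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
write_sim_bundle <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  expr <- gen_expression_datasets(cfg)
  for (ds in expr$datasets) {
    write_expression(ds,
                     file.path(out_dir, paste0(ds$dataset_id, "_matrix.tsv")),
                     file.path(out_dir, paste0(ds$dataset_id, "_meta.tsv")))
  }
  genes <- expr$truth$gene
  blocks <- split(genes, ceiling(seq_along(genes) / 25))
  names(blocks) <- sprintf("band_%02d", seq_along(blocks))
  write_gene_sets(list(universe = genes, sets = blocks),
                  file.path(out_dir, "gene_sets.gmt"))
  net <- gen_network(cfg)
  write_network(net$graph, file.path(out_dir, "edges.tsv"))
  ihc <- gen_ihc_cohort(cfg)
  data.table::fwrite(ihc$table, file.path(out_dir, "ihc.csv"))
  surv <- gen_survival_cohort(cfg)
  data.table::fwrite(surv$cohort, file.path(out_dir, "survival.csv"))
  truth <- list(seed = cfg$seed,
                gene_roles = table(expr$truth$role),
                planted_hubs = net$hubs,
                ihc_operating_point = c(sens = cfg$ihc_sens,
                                        spec = cfg$ihc_spec),
                surv_log_hr = cfg$surv_log_hr)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, force = TRUE)
  cs_log("write_sim_bundle: bundle written to %s (seed %d)", out_dir, cfg$seed)
  invisible(list(expression = expr, network = net, ihc = ihc, survival = surv))
}
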