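#' Full pipeline configuration
#'
#' Bundles every tunable parameter of the prediction pipeline. All
#' fields have defaults, so `run_config()` runs the synthetic fixture
#' end-to-end unchanged.
#'
#' @param gamma_prime_m,gamma_prime_d Raw GIP bandwidths for the microbe
#'   and disease kernels (default 1).
#' @param wknn A [wknn_config()].
#' @param graph List with `p` (neighbourhood size, default 5),
#'   `density_threshold` (0.5) and `merge_overlap` (0.8) for
#'   [build_regularization_graph()].
#' @param solver A [solver_config()].
#' @param top_n Length of per-disease prediction lists written by
#'   [run_predict()] (default 10).
#' @return A `run_config` list.
#' @export
run_config <- function(gamma_prime_m = 1, gamma_prime_d = 1,
                       wknn = wknn_config(),
                       graph = list(p = 5, density_threshold = 0.5,
                                    merge_overlap = 0.8),
                       solver = solver_config(), top_n = 10) {
  stopifnot(gamma_prime_m > 0, gamma_prime_d > 0,
            inherits(wknn, "wknn_config"), inherits(solver, "solver_config"))
  graph <- utils::modifyList(list(p = 5, density_threshold = 0.5,
                                  merge_overlap = 0.8), graph)
  structure(list(gamma_prime_m = gamma_prime_m,
                 gamma_prime_d = gamma_prime_d,
                 wknn = wknn, graph = graph, solver = solver,
                 top_n = as.integer(top_n)),
            class = "run_config")
}

#' Read a key: value configuration file
#'
#' Flat `key: value` lines (one per line, `#` comments allowed) with
#' dotted keys for nested sections, e.g. `solver.rank_k: 10` or
#' `wknn.K: 5`. Unknown keys raise an error. Values are parsed as
#' numerics where possible.
#'
#' @param path Path to the configuration file.
#' @param base A `run_config` supplying defaults for unset keys.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, base = run_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  cfg <- base
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) < 2)
      stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    cfg <- set_config_key(cfg, parts, val)
  }
  # re-validate through the constructors
  run_config(gamma_prime_m = cfg$gamma_prime_m,
             gamma_prime_d = cfg$gamma_prime_d,
             wknn = do.call(wknn_config, unclass(cfg$wknn)),
             graph = cfg$graph,
             solver = do.call(solver_config, unclass(cfg$solver)),
             top_n = cfg$top_n)
}

set_config_key <- function(cfg, parts, val) {
  if (length(parts) == 1) {
    if (!parts %in% names(cfg))
      stop("unknown config key: ", parts, call. = FALSE)
    cfg[[parts]] <- val
  } else {
    if (!parts[1] %in% names(cfg) || !parts[2] %in% names(cfg[[parts[1]]]))
      stop("unknown config key: ", paste(parts, collapse = "."),
           call. = FALSE)
    cfg[[parts[1]]][[parts[2]]] <- val
  }
  cfg
}

#' Run the prediction pipeline end-to-end
#'
#' Reads (or accepts) an association table and optional external disease
#' similarity, runs the full pipeline, and writes the score matrix,
#' per-disease top-N prediction lists, and a JSON metadata sidecar
#' (resolved configuration, seed, iteration count, final objective) to
#' `out_dir`.
#'
#' @param association Path to an association TSV or an
#'   `association_table`.
#' @param sdm Path to a disease-similarity TSV, a labelled matrix, or
#'   `NULL`.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   file output.
#' @param config A [run_config()].
#' @param new_disease Optional disease label whose known associations are
#'   removed before the run (the "new disease" protocol: prediction for
#'   that disease then relies only on the remaining network and the
#'   similarity information).
#' @return Invisibly, a list with `scores`, `fit`, `Y`, `rankings` (list
#'   of per-disease data frames), and `metadata`.
#' @export
run_predict <- function(association, sdm = NULL, out_dir = NULL,
                        config = run_config(), new_disease = NULL) {
  table <- if (is.character(association))
    read_association_table(association) else association
  Y <- build_adjacency(table)
  if (is.character(sdm)) sdm <- read_score_matrix(sdm)
  if (!is.null(new_disease)) {
    if (!new_disease %in% colnames(Y))
      stop("unknown disease label: ", new_disease, call. = FALSE)
    Y[, new_disease] <- 0
    if (all(Y == 0))
      stop("removing ", new_disease, " leaves no known associations",
           call. = FALSE)
  }
  res <- tryCatch(pipeline_scores(Y, sdm, config),
                  error = function(e)
                    stop("pipeline stage failed: ", conditionMessage(e),
                         call. = FALSE))
  rankings <- lapply(colnames(Y), function(d)
    rank_predictions(res$scores, Y, d, top = config$top_n))
  names(rankings) <- colnames(Y)
  metadata <- list(
    config = config_as_list(config),
    new_disease = new_disease,
    n_microbes = nrow(Y), n_diseases = ncol(Y),
    n_known = sum(Y),
    iterations_run = res$fit$iterations_run,
    converged = res$fit$converged,
    final_objective =
      res$fit$objective_trace[length(res$fit$objective_trace)])
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_score_matrix(res$scores, file.path(out_dir, "scores.tsv"))
    ranked <- do.call(rbind, lapply(names(rankings), function(d)
      cbind(disease = d, rankings[[d]])))
    utils::write.table(ranked, file.path(out_dir, "top_predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(metadata, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(scores = res$scores, fit = res$fit, Y = Y,
                 rankings = rankings, metadata = metadata))
}

#' Run LOOCV evaluation end-to-end
#'
#' Wraps [loocv()] with file input/output: writes the per-fold rank
#' report, the ROC points, and a JSON metadata sidecar including the
#' AUC.
#'
#' @inheritParams run_predict
#' @param mode `"global"` or `"local"`.
#' @param fast_mode Passed to [loocv()].
#' @return Invisibly, the `loocv_result`.
#' @export
run_evaluate <- function(association, sdm = NULL, out_dir = NULL,
                         mode = c("global", "local"),
                         config = run_config(), fast_mode = FALSE) {
  mode <- match.arg(mode)
  table <- if (is.character(association))
    read_association_table(association) else association
  if (is.character(sdm)) sdm <- read_score_matrix(sdm)
  res <- loocv(table, sdm, mode = mode, config = config,
               fast_mode = fast_mode)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_loocv_report(res,
                       file.path(out_dir, paste0("loocv_", mode, "_ranks.tsv")),
                       file.path(out_dir, paste0("loocv_", mode, "_roc.tsv")))
    jsonlite::write_json(
      list(config = config_as_list(config), mode = mode,
           fast_mode = fast_mode, n_folds = nrow(res$per_fold_ranks),
           auc = res$auc),
      file.path(out_dir, paste0("loocv_", mode, "_metadata.json")),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(res)
}

config_as_list <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  strip(config)
}

#' Write a synthetic fixture to disk
#'
#' Emits the three standard files consumed by the other stages: the
#' association table, the ground-truth score matrix, and the disease
#' similarity matrix, all TSV.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory.
#' @return Invisibly, the generated fixture list.
#' @export
write_fixture <- function(spec = fixture_spec(), out_dir) {
  fx <- generate_fixture(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_association_table(fx$table, file.path(out_dir, "associations.tsv"))
  write_score_matrix(fx$truth, file.path(out_dir, "truth_scores.tsv"))
  write_score_matrix(fx$sdm, file.path(out_dir, "disease_similarity.tsv"))
  jsonlite::write_json(unclass(spec), file.path(out_dir, "fixture_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fx)
}
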