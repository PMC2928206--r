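# End-to-end orchestration: simulate -> amplitudes -> significance -> mlm ->
# mars -> knockout, with a JSON config, deterministic seeding and a
# provenance manifest.

#' Read a BED12-like gene table
#'
#' Columns: chrom, start, end, name, score, strand, alt_starts, alt_ends
#' (comma-separated genomic coordinates; 0-based half-open).
#' @param path TSV path.
#' @return a `cv_gene_models` data.frame.
#' @export
read_gene_table <- function(path) {
  g <- data.table::fread(path, sep = "\t", data.table = FALSE)
  gm <- data.frame(gene_id = g$name, chrom = g$chrom, start = g$start,
                   end = g$end, strand = g$strand, stringsAsFactors = FALSE)
  gm$start_sites <- lapply(strsplit(as.character(g$alt_starts), ","), as.numeric)
  gm$stop_sites <- lapply(strsplit(as.character(g$alt_ends), ","), as.numeric)
  gm$chosen_tss <- vapply(gm$start_sites, `[[`, numeric(1), 1L)
  gm$chosen_tes <- vapply(gm$stop_sites, `[[`, numeric(1), 1L)
  class(gm) <- c("cv_gene_models", "data.frame")
  gm
}

#' Read BED6 tag intervals
#' @param path BED path (plain text).
#' @export
read_bed <- function(path) {
  b <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  names(b)[seq_len(min(6L, ncol(b)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6L, ncol(b)))]
  b
}

#' Read per-mark binned profile matrices
#' @param dir directory containing `profile_<mark>.tsv` files.
#' @export
read_profiles_dir <- function(dir) {
  files <- list.files(dir, pattern = "^profile_.*\\.tsv$", full.names = TRUE)
  if (!length(files)) stop_invalid("no profile_<mark>.tsv files in ", dir)
  marks <- sub("^profile_(.*)\\.tsv$", "\\1", basename(files))
  out <- lapply(files, function(f)
    as.matrix(data.table::fread(f, sep = "\t", header = FALSE,
                                data.table = FALSE)))
  stats::setNames(out, marks)
}

#' Read a probe-level expression table
#' @param path TSV with columns probe_id, log2_expr and optionally gene_id.
#' @export
read_expression_tsv <- function(path) {
  e <- data.table::fread(path, sep = "\t", data.table = FALSE)
  if (!all(c("probe_id", "log2_expr") %in% names(e)))
    stop_invalid("expression table needs probe_id and log2_expr columns")
  if (is.null(e$gene_id)) e$gene_id <- e$probe_id
  e
}

#' @noRd
write_tsv <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t")
  path
}

#' @noRd
model_to_json <- function(model) {
  if (inherits(model, "cv_mlmodel")) {
    list(type = "multilinear", terms = model$terms,
         beta = as.list(round(model$beta, 10)),
         train_mse = mean(model$train_mse), test_mse = mean(model$test_mse),
         train_adj_r2 = mean(model$train_adj_r2),
         test_adj_r2 = mean(model$test_adj_r2), meta = model$meta)
  } else {
    list(type = "mars",
         bases = lapply(model$all_bases[lengths(model$all_bases) > 0],
                        function(b) lapply(b, function(f)
                          list(mark = f$mark, knot = f$knot, dir = f$dir))),
         coefficients = as.list(round(model$coefficients, 10)),
         gcv = model$gcv, rss = model$rss, mse = model$mse, r2 = model$r2,
         penalty = model$penalty, enp_formula = model$enp_formula)
  }
}

#' Default pipeline configuration
#'
#' @param out_dir run directory.
#' @param seed master seed; every stage derives its own child seed.
#' @param ... overrides for any default listed below.
#' @return config list for [run_all()].
#' @export
run_config <- function(out_dir, seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir, seed = seed,
    synthetic = list(n_genes = 2000L, n_body_bins = 300L, flank_bins = 20L),
    fdr_cutoff = 0.05, mode_estimator = "hsm",
    mlm = list(n_runs = 100L, survival_cutoff = 0.35, init_size = 30L,
               folds = 10L, runs_per_fold = 10L, extra_random_terms = 60L,
               retention = 5L),
    mars = list(max_degree = 3L, penalty = 3, max_terms = 21L,
                max_knots = 20L),
    paths = NULL)
  mods <- list(...)
  for (nm in names(mods)) cfg[[nm]] <- utils::modifyList(
    if (is.list(cfg[[nm]]) && is.list(mods[[nm]])) cfg[[nm]] else list(),
    if (is.list(mods[[nm]])) mods[[nm]] else stats::setNames(list(mods[[nm]]), nm)
  )
  for (nm in names(mods)) if (!is.list(mods[[nm]])) cfg[[nm]] <- mods[[nm]]
  cfg
}

#' Run the full pipeline
#'
#' Executes simulate (when no input paths are given) -> amplitudes ->
#' significance -> multilinear model -> MARS -> knockout screens, writing each
#' stage's tables under `config$out_dir` plus a `manifest.json` echoing every
#' tunable, seed and decision. Any stage failure aborts with the stage name;
#' outputs written before the failure remain on disk.
#'
#' @param config list from [run_config()] or a path to a JSON config.
#' @return (invisibly) list with the fitted models, amplitudes, significance
#'   calls and knockout screens.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  manifest <- list(package = "chromvalence",
                   version = as.character(utils::packageVersion("chromvalence")),
                   seed = seed, config = config[setdiff(names(config), "out_dir")],
                   decisions = list(
                     mode_estimator = config$mode_estimator %||% "hsm",
                     enp_formula = "enp = T + penalty * n_hinge_pairs",
                     trim_rule = "drop single min and max across folds",
                     tes_tie_break = "longest body"),
                   warnings = character(), timings = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }

  # --- simulate / load ------------------------------------------------------
  if (is.null(config$paths)) {
    dataset <- stage("simulate", {
      syn <- config$synthetic %||% list()
      ds <- simulate_dataset(n_genes = syn$n_genes %||% 2000L,
                             n_body_bins = syn$n_body_bins %||% 300L,
                             flank_bins = syn$flank_bins %||% 20L,
                             target_r2 = syn$target_r2 %||% 0.5,
                             seed = child_seed(seed, "simulate"))
      write_dataset(ds, file.path(out, "synthetic"))
      ds
    })
    profiles <- dataset$profiles
    expression <- dataset$expression
  } else {
    dataset <- NULL
    profiles <- stage("load", {
      pr <- read_profiles_dir(config$paths$profiles)
      if (!is.null(config$paths$genes)) {
        ids <- read_gene_table(config$paths$genes)$gene_id
        pr <- lapply(pr, function(m) { rownames(m) <- ids; m })
      }
      pr
    })
    expression <- NULL  # loaded inside the mlm stage
  }

  # --- amplitudes -----------------------------------------------------------
  amps <- stage("amplitudes", {
    am <- amplitude_matrix(profiles)
    write_tsv(cbind(gene_id = rownames(am$amplitudes) %||%
                      seq_len(nrow(am$amplitudes)), as.data.frame(am$amplitudes)),
              file.path(out, "amplitudes.tsv"))
    write_tsv(as.data.frame(am$cv_rmsd), file.path(out, "cv_rmsd.tsv"))
    for (mk in names(am$templates))
      write_tsv(data.frame(position = seq_along(am$templates[[mk]]$values),
                           value = am$templates[[mk]]$values),
                file.path(out, paste0("template_", mk, ".tsv")))
    am
  })
  A <- amps$amplitudes

  # --- significance ---------------------------------------------------------
  sig <- stage("significance", {
    s <- significance_calls(A, fdr_cutoff = config$fdr_cutoff %||% 0.05,
                            mode_estimator = config$mode_estimator %||% "hsm")
    long <- data.frame(gene = rep(rownames(A) %||% seq_len(nrow(A)), ncol(A)),
                       mark = rep(colnames(A), each = nrow(A)),
                       amplitude = as.numeric(A), p = as.numeric(s$p),
                       q = as.numeric(s$q), significant = as.logical(s$flag))
    write_tsv(long, file.path(out, "significance.tsv"))
    s
  })

  # --- multilinear ----------------------------------------------------------
  mlm_cfg <- config$mlm %||% list()
  ml <- stage("mlm", {
    if (is.null(expression)) {
      if (is.null(config$paths$expression) ||
          !file.exists(config$paths$expression))
        stop("expression file not found: ",
             config$paths$expression %||% "<missing>")
      expression <- read_expression_tsv(config$paths$expression)
    }
    probe_A <- A[match(expression$gene_id, rownames(A) %||%
                         as.character(seq_len(nrow(A)))), , drop = FALSE]
    if (anyNA(probe_A)) stop("expression gene ids missing from amplitudes")
    terms <- enumerate_terms(colnames(A))
    design <- build_design(probe_A, terms)
    y <- expression$log2_expr
    r1 <- round1_survival(design, y, terms,
                          n_runs = mlm_cfg$n_runs %||% 100L,
                          cutoff = mlm_cfg$survival_cutoff %||% 0.35,
                          init_size = mlm_cfg$init_size %||% 30L,
                          seed = child_seed(seed, "round1"))
    model <- cv_protocol(design, y, terms, starting_terms = r1$surviving,
                         n_folds = mlm_cfg$folds %||% 10L,
                         runs_per_fold = mlm_cfg$runs_per_fold %||% 10L,
                         extra_random_terms = mlm_cfg$extra_random_terms %||% 60L,
                         retention = mlm_cfg$retention %||% 5L,
                         gene_ids = expression$gene_id,
                         seed = child_seed(seed, "cv"))
    jsonlite::write_json(model_to_json(model), file.path(out, "ml_model.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_tsv(term_statistics(model, probe_A), file.path(out, "ml_terms.tsv"))
    write_tsv(data.frame(fold = seq_along(model$train_mse),
                         train_mse = model$train_mse,
                         test_mse = model$test_mse,
                         train_adj_r2 = model$train_adj_r2,
                         test_adj_r2 = model$test_adj_r2),
              file.path(out, "ml_folds.tsv"))
    write_tsv(data.frame(term = names(r1$rates), survival = r1$rates),
              file.path(out, "ml_survival.tsv"))
    list(model = model, probe_A = probe_A, y = y)
  })

  # --- mars -----------------------------------------------------------------
  mars_cfg <- config$mars %||% list()
  mars <- stage("mars", {
    m <- fit_mars(ml$probe_A, ml$y,
                  max_degree = mars_cfg$max_degree %||% 3L,
                  penalty = mars_cfg$penalty %||% 3,
                  max_terms = mars_cfg$max_terms %||% 21L,
                  max_knots = mars_cfg$max_knots %||% 20L)
    jsonlite::write_json(model_to_json(m), file.path(out, "mars_model.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep <- mars_report(m, ml$probe_A)
    write_tsv(rep$bases, file.path(out, "mars_bases.tsv"))
    write_tsv(rep$impact, file.path(out, "mars_impact.tsv"))
    m
  })

  # --- knockout -------------------------------------------------------------
  kos <- stage("knockout", {
    scr_ml <- knockout_screen(ml$model, ml$probe_A, pairs = TRUE)
    scr_mars <- knockout_screen(mars, ml$probe_A, pairs = TRUE)
    write_tsv(scr_ml, file.path(out, "knockout_ml.tsv"))
    write_tsv(scr_mars, file.path(out, "knockout_mars.tsv"))
    list(ml = scr_ml, mars = scr_mars)
  })

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = dataset, amplitudes = amps, significance = sig,
                 ml_model = ml$model, mars_model = mars, knockouts = kos,
                 manifest = manifest))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run-all` (others are reachable through `run-all`;
#' each stage also has a direct R API). Arguments are `--key value` pairs;
#' `--config file.json` supplies a full [run_config()] list.
#'
#' @param args character vector (default: command line).
#' @return exit status, invisibly.
#' @export
cv_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: chromvalence <simulate|run-all> [--config cfg.json]",
        "[--out-dir DIR] [--n-genes N] [--seed S]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  kv <- args[-1]
  opts <- list()
  i <- 1L
  while (i <= length(kv)) {
    key <- sub("^--", "", kv[i])
    opts[[gsub("-", "_", key)]] <- if (i + 1L <= length(kv)) kv[i + 1L] else ""
    i <- i + 2L
  }
  seed <- as.integer(opts$seed %||% 1L)
  out_dir <- opts$out_dir %||% "chromvalence_run"
  if (cmd == "simulate") {
    ds <- simulate_dataset(n_genes = as.integer(opts$n_genes %||% 2000L),
                           seed = seed)
    write_dataset(ds, out_dir)
    cat("wrote synthetic dataset to", out_dir, "\n")
  } else if (cmd == "run-all") {
    cfg <- if (!is.null(opts$config)) opts$config else {
      c <- run_config(out_dir, seed = seed)
      if (!is.null(opts$n_genes))
        c$synthetic$n_genes <- as.integer(opts$n_genes)
      c
    }
    run_all(cfg)
    cat("pipeline complete:", out_dir, "\n")
  } else {
    cat("unknown subcommand:", cmd, "\n")
    return(invisible(1L))
  }
  invisible(0L)
}
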