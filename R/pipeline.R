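#' Run the full screen end to end
#'
#' Executes the method's complete flow on one expression matrix:
#' consensus clustering of the samples in the prior-gene feature space (at
#' a fixed `k`, the method's visually chosen cluster number), differential
#' expression between the two clusters, the genome-wide per-gene screen,
#' and the final candidate-set assembly.  All stage outputs are written
#' under `out_dir` together with a JSON run manifest (tool version, config
#' fingerprint, input fingerprints, per-stage wall times, seeds, output
#' paths).  The screen stage streams per-gene records to a checkpoint, so
#' an interrupted or repeated run with unchanged inputs resumes without
#' recomputing finished targets.  Any stage error aborts with the stage
#' name after persisting the manifest so far.
#'
#' @param expr expression matrix or path to a TSV readable by
#'   [read_expression()].
#' @param prior prior [gene_set()] or path to a GMT file.
#' @param out_dir output directory.
#' @param k number of sample clusters for the DE stage (default 2).
#' @param screen a [screen_config()].
#' @param cluster a [consensus_config()].
#' @param de a [de_config()].
#' @param workers parallel workers for the screen stage.
#' @param set_name GMT set name, when `prior` is a path to a multi-set file.
#' @return an object of class `rfgsea_run`: `manifest`, `candidates`,
#'   `screen`, `de`, `labels`, `consensus`.
#' @export
run_all <- function(expr, prior, out_dir, k = 2L,
                    screen = screen_config(), cluster = consensus_config(),
                    de = de_config(), workers = 1L, set_name = NULL) {
  if (is.character(expr)) expr <- read_expression(expr)
  if (is.character(prior)) prior <- read_gene_set(prior, set_name)
  validate_expression_matrix(expr)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg <- list(k = as.integer(k), screen = screen, cluster = cluster, de = de)
  manifest <- list(
    tool = "rfgsea", version = as.character(utils::packageVersion("rfgsea")),
    config_hash = config_hash(cfg),
    seeds = list(screen = screen$root_seed, cluster = cluster$seed),
    inputs = list(
      expression = sprintf("%dx%d matrix, fingerprint %s", nrow(expr),
                           ncol(expr), config_hash(list(dim(expr),
                                                        sum(expr),
                                                        sum(expr^2)))),
      prior = sprintf("set '%s', %d genes, fingerprint %s", prior$name,
                      length(prior$genes), config_hash(prior$genes))),
    stages = list(), outputs = character(0))
  persist <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- function(name, code) {
    t0 <- Sys.time()
    res <- tryCatch(code, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      persist()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
    res
  }
  emit <- function(path) {
    manifest$outputs <<- c(manifest$outputs, path)
    path
  }

  res_cluster <- stage("cluster", {
    feats <- restrict_to_universe(prior, expr, screen$min_set_size)
    cm <- consensus_matrix(expr[feats$genes, , drop = FALSE], k, cluster)
    labels <- final_labels(cm, k)
    write_tsv_with_header(
      data.frame(sample = colnames(cm), as.data.frame(unclass(cm))),
      emit(file.path(out_dir, sprintf("consensus_k%d.tsv", k))),
      manifest$config_hash)
    write_tsv_with_header(
      data.frame(sample = names(labels), cluster = unname(labels)),
      emit(file.path(out_dir, "cluster_labels.tsv")), manifest$config_hash)
    list(cm = cm, labels = labels)
  })

  res_de <- stage("diffexp", {
    det <- differential_expression(expr, res_cluster$labels, de)
    write_tsv_with_header(det, emit(file.path(out_dir, "degs.tsv")),
                          manifest$config_hash)
    writeLines(significant_genes(det),
               emit(file.path(out_dir, "degs_genes.txt")))
    det
  })

  res_screen <- stage("screen", {
    st <- screen_all(expr, prior, screen,
                     checkpoint_path = file.path(out_dir,
                                                 "screen_checkpoint.tsv"),
                     workers = workers)
    write_tsv_with_header(st, emit(file.path(out_dir, "screen.tsv")),
                          manifest$config_hash)
    st
  })

  cands <- stage("assemble", {
    cs <- assemble_candidates(res_screen, significant_genes(res_de))
    write_candidate_sets(cs, file.path(out_dir, "candidates"))
    for (nm in names(cs)) {
      emit(file.path(out_dir, "candidates", paste0(nm, ".txt")))
    }
    emit(file.path(out_dir, "candidates", "venn_counts.tsv"))
    cs
  })

  stopifnot(all(file.exists(manifest$outputs)))
  persist()
  structure(list(manifest = manifest, candidates = cands,
                 screen = res_screen, de = res_de,
                 labels = res_cluster$labels, consensus = res_cluster$cm),
            class = "rfgsea_run")
}

#' @export
print.rfgsea_run <- function(x, ...) {
  cat("<rfgsea_run>", length(x$candidates$final), "final candidate gene(s);",
      length(x$manifest$outputs), "output files\n")
  invisible(x)
}

#' Power and error report over simulated studies
#'
#' For runs on planted-module studies: sensitivity (module genes recovered
#' over module size), decoy rejection rate (prior decoys kept out of the
#' final list) and background contamination (final genes outside the
#' module).  For runs on null studies: the fraction of genes reaching the
#' final list, the empirical type-I behaviour of the full intersection.
#' Aggregate rates carry exact Clopper-Pearson 95% intervals.
#'
#' @param runs list of `rfgsea_run` (or `candidate_sets`) objects.
#' @param truths list of matching `simulated_study` objects; an absent
#'   truth is an error.
#' @return an object of class `benchmark_report`: `per_run` and `summary`
#'   data.frames.
#' @export
benchmark_report <- function(runs, truths) {
  stopifnot(length(runs) >= 1L, length(runs) == length(truths))
  per <- lapply(seq_along(runs), function(i) {
    truth <- truths[[i]]
    if (!inherits(truth, "simulated_study")) {
      stop("truth for run ", i, " is missing or not a simulated_study")
    }
    cands <- if (inherits(runs[[i]], "rfgsea_run")) runs[[i]]$candidates
             else runs[[i]]
    final <- cands$final
    module <- truth$module_genes
    decoys <- setdiff(truth$prior$genes, module)
    n_genes <- nrow(truth$matrix)
    data.frame(
      run = i,
      null = length(module) == 0L,
      n_final = length(final),
      sensitivity = if (length(module)) length(intersect(final, module)) /
        length(module) else NA_real_,
      contamination = if (length(final)) length(setdiff(final, module)) /
        length(final) else 0,
      decoy_rejection = if (length(decoys)) 1 - length(intersect(final,
                                                                 decoys)) /
        length(decoys) else NA_real_,
      final_fraction = length(final) / n_genes)
  })
  per <- do.call(rbind, per)

  ci_rate <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    ci <- stats::binom.test(x, n)$conf.int
    c(x / n, ci[1], ci[2])
  }
  planted <- per[!per$null, , drop = FALSE]
  rows <- list()
  if (nrow(planted)) {
    mod_sizes <- vapply(truths[!per$null], function(t)
      length(t$module_genes), integer(1))
    hits <- round(planted$sensitivity * mod_sizes)
    s <- ci_rate(sum(hits), sum(mod_sizes))
    rows$sensitivity <- data.frame(metric = "sensitivity", estimate = s[1],
                                   ci_lo = s[2], ci_hi = s[3],
                                   n = sum(mod_sizes))
    fp <- round(planted$contamination * planted$n_final)
    cc <- ci_rate(sum(fp), max(sum(planted$n_final), 1))
    rows$contamination <- data.frame(metric = "contamination",
                                     estimate = cc[1], ci_lo = cc[2],
                                     ci_hi = cc[3], n = sum(planted$n_final))
  }
  nulls <- per[per$null, , drop = FALSE]
  if (nrow(nulls)) {
    tot_g <- sum(vapply(truths[per$null], function(t) nrow(t$matrix),
                        integer(1)))
    nn <- ci_rate(sum(nulls$n_final), tot_g)
    rows$null_rate <- data.frame(metric = "null_final_fraction",
                                 estimate = nn[1], ci_lo = nn[2],
                                 ci_hi = nn[3], n = tot_g)
  }
  structure(list(per_run = per, summary = do.call(rbind, rows)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>", nrow(x$per_run), "run(s)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark report
#'
#' @param report a `benchmark_report`.
#' @param dir output directory; writes `benchmark_per_run.tsv`,
#'   `benchmark_summary.tsv` and a plain-text summary.
#' @return the directory, invisibly.
#' @export
write_benchmark_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_with_header(report$per_run,
                        file.path(dir, "benchmark_per_run.tsv"))
  write_tsv_with_header(report$summary,
                        file.path(dir, "benchmark_summary.tsv"))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "benchmark_summary.txt"))
  invisible(dir)
}
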