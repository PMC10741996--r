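#' Parameters of the planted-module study generator
#'
#' The generator emulates the premise that genes of one biological process
#' are mutually predictive: module genes load on a shared latent factor,
#' background genes are independent noise, and the prior set mixes true
#' module members with decoys, mirroring the mixed-confidence tiers of
#' curated process-gene databases.  An optional mean shift on the latent
#' factor gives the two sample groups the separation that the clustering
#' and differential-expression stages consume.
#'
#' @param n_genes total genes (default 200).
#' @param n_samples total samples, split evenly into two groups (default
#'   120).
#' @param module_size planted module size (default 30).
#' @param prior_true module members included in the prior set (default 20).
#' @param prior_decoys background genes included in the prior set (default
#'   10).
#' @param beta_range range of module factor loadings (default 0.6-1.2).
#' @param noise_sd background standard deviation (default 1); module
#'   residual noise uses half this value so per-gene marginal variances are
#'   comparable and the module is not discoverable by variance alone.
#' @param group_shift latent-factor mean of group 2 (default 2; 0 removes
#'   the group structure).
#' @param seed integer seed.
#' @return an object of class `simulation_params`.
#' @export
simulation_params <- function(n_genes = 200L, n_samples = 120L,
                              module_size = 30L, prior_true = 20L,
                              prior_decoys = 10L,
                              beta_range = c(0.6, 1.2), noise_sd = 1,
                              group_shift = 2, seed = 1L) {
  stopifnot(module_size < n_genes, prior_true <= module_size,
            prior_true + prior_decoys >= 5L, noise_sd > 0,
            length(beta_range) == 2L, beta_range[1] <= beta_range[2],
            n_samples >= 6L)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 module_size = as.integer(module_size),
                 prior_true = as.integer(prior_true),
                 prior_decoys = as.integer(prior_decoys),
                 beta_range = as.numeric(beta_range),
                 noise_sd = noise_sd, group_shift = group_shift,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

.assemble_study <- function(params, module_size) {
  p <- params
  n <- p$n_genes
  s <- p$n_samples
  genes <- sprintf("G%04d", seq_len(n))
  samples <- sprintf("S%03d", seq_len(s))
  group <- rep(1:2, c(ceiling(s / 2), floor(s / 2)))
  z <- rnorm(s, mean = ifelse(group == 2, p$group_shift, 0), sd = 1)
  mat <- matrix(rnorm(n * s, sd = p$noise_sd), n, s,
                dimnames = list(genes, samples))
  module <- character(0)
  if (module_size > 0) {
    idx <- sort(sample.int(n, module_size))
    module <- genes[idx]
    beta <- runif(module_size, p$beta_range[1], p$beta_range[2])
    mat[idx, ] <- outer(beta, z) +
      matrix(rnorm(module_size * s, sd = p$noise_sd * 0.5), module_size, s)
  }
  background <- setdiff(genes, module)
  true_in_prior <- if (p$prior_true > 0 && module_size > 0)
    sort(sample(module, p$prior_true)) else character(0)
  decoys <- sort(sample(background, p$prior_decoys +
                          (p$prior_true - length(true_in_prior))))
  prior_genes <- c(true_in_prior, decoys)
  tiers <- stats::setNames(
    rep_len(c("validated", "screened", "deduced"), length(prior_genes)),
    prior_genes)
  study <- structure(
    list(matrix = mat,
         module_genes = module,
         prior = gene_set("planted_module_prior", prior_genes, tiers),
         group_labels = stats::setNames(group, samples),
         params = p),
    class = "simulated_study")
  suppressMessages(validate_expression_matrix(mat))
  study
}

#' Generate a planted-module expression study
#'
#' Per sample s, a latent factor `z_s ~ Normal(mu_group, 1)` with group
#' means 0 and `group_shift`; module gene g measures
#' `beta_g * z_s + Normal(0, noise_sd/2)` with
#' `beta_g ~ Uniform(beta_range)`; background genes are independent
#' `Normal(0, noise_sd)`.  Fully reproducible from `params$seed`.
#'
#' @param params a [simulation_params()].
#' @return an object of class `simulated_study`: `matrix`, `module_genes`
#'   (ground truth), `prior` (a [gene_set()] of `prior_true` module members
#'   plus `prior_decoys` background decoys, tiers assigned round-robin),
#'   `group_labels`, `params`.
#' @export
simulate_study <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, .assemble_study(params, params$module_size))
}

#' Generate a null study (no planted module)
#'
#' Every gene is independent background noise; the prior set is still
#' emitted (all decoys), so the type-I behaviour of the full screen is
#' measurable.
#'
#' @param params a [simulation_params()].
#' @return a `simulated_study` with empty `module_genes`.
#' @export
simulate_null_study <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, .assemble_study(params, 0L))
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study>", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples;", length(x$module_genes), "module genes;",
      length(x$prior$genes), "prior genes\n")
  invisible(x)
}

#' Write a simulated study to a directory
#'
#' Writes `expr.tsv`, `prior.gmt`, `truth.tsv` (gene, is_module, in_prior,
#' tier) and `labels.tsv`.
#'
#' @param study a `simulated_study`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(study$matrix, file.path(dir, "expr.tsv"))
  writeLines(paste(c(study$prior$name, "synthetic planted-module prior",
                     study$prior$genes), collapse = "\t"),
             file.path(dir, "prior.gmt"))
  genes <- rownames(study$matrix)
  tier <- rep(NA_character_, length(genes))
  tier[match(names(study$prior$tiers), genes)] <- study$prior$tiers
  write_tsv_with_header(
    data.frame(gene = genes,
               is_module = genes %in% study$module_genes,
               in_prior = genes %in% study$prior$genes,
               tier = tier),
    file.path(dir, "truth.tsv"))
  write_tsv_with_header(
    data.frame(sample = names(study$group_labels),
               group = unname(study$group_labels)),
    file.path(dir, "labels.tsv"))
  invisible(dir)
}
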