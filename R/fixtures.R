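#' Specification of the two-gene inhibition toy data set
#'
#' Emulates the classic situation where two genes co-cluster in DNA
#' methylation (a shared epigenetic factor) while their mRNA expression is
#' anti-correlated because gene A's product inhibits gene B's expression —
#' the pattern a coordinated, sortable CircleMap reveals with a single
#' sort that a clustered heatmap obscures.
#'
#' The generative model is a Gaussian structural-equation scheme on
#' standardized variables: a shared latent factor gives methylation of A
#' and B a correlation of `rho_meth`; expression of A loads on methylation
#' of A with path coefficient `rho_meth_expr` (negative); expression of B
#' loads on expression of A with coefficient `rho_inhibit` (negative, the
#' inhibition) and on methylation of B with `rho_meth_expr`. Residual
#' variances are set so every signal has unit variance; a combination
#' whose implied residual variance is negative is rejected as infeasible.
#' Observed values add measurement noise of standard deviation `noise_sd`.
#'
#' @param n_samples number of samples (>= 4).
#' @param rho_meth methylation-methylation correlation target, in `[0, 1)`.
#' @param rho_meth_expr methylation-to-expression path coefficient,
#'   negative, in `(-1, 1)`.
#' @param rho_inhibit expression(A)-to-expression(B) path coefficient,
#'   negative, in `(-1, 1)`.
#' @param noise_sd measurement noise standard deviation (> 0).
#' @param n_background additional background genes following the dominant
#'   methylation-up/expression-down pattern, filling out the heatmap-like
#'   matrices.
#' @param seed integer seed; all randomness flows from it.
#' @return a list of class `toy_spec`.
#' @export
toy_spec <- function(n_samples = 10L, rho_meth = 0.8, rho_meth_expr = -0.8,
                     rho_inhibit = -0.8, noise_sd = 0.3, n_background = 8L,
                     seed = 1L) {
  if (n_samples < 4L) stop("n_samples must be >= 4", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  for (r in c(rho_meth, rho_meth_expr, rho_inhibit))
    if (abs(r) >= 1) stop("correlations must lie in (-1, 1)", call. = FALSE)
  if (rho_meth < 0) stop("rho_meth must be nonnegative", call. = FALSE)
  # residual variance of expr(B) under unit-variance standardization
  c_ea_mb <- rho_meth_expr * rho_meth  # corr(expr A, meth B)
  v <- rho_inhibit^2 + rho_meth_expr^2 + 2 * rho_inhibit * rho_meth_expr * c_ea_mb
  if (v > 1)
    stop("infeasible coupling combination: implied covariance is not positive semi-definite",
         call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), rho_meth = rho_meth,
                 rho_meth_expr = rho_meth_expr, rho_inhibit = rho_inhibit,
                 noise_sd = noise_sd, n_background = as.integer(n_background),
                 seed = as.integer(seed)),
            class = "toy_spec")
}

#' Generate the two-gene inhibition toy data set
#'
#' @param spec a [toy_spec].
#' @return list with elements `methylation` and `expression` (two
#'   [omics_matrix] objects over the same samples), `graph` (a
#'   [pathway_graph] in which GENEA inhibits GENEB) and `spec`.
#' @export
generate_toy <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  l <- sqrt(spec$rho_meth)
  s <- sqrt(1 - spec$rho_meth)
  a <- spec$rho_meth_expr
  M <- stats::rnorm(n)
  mA <- l * M + s * stats::rnorm(n)
  mB <- l * M + s * stats::rnorm(n)
  eA <- a * mA + sqrt(1 - a^2) * stats::rnorm(n)
  c_ea_mb <- a * spec$rho_meth
  v <- spec$rho_inhibit^2 + a^2 + 2 * spec$rho_inhibit * a * c_ea_mb
  eB <- spec$rho_inhibit * eA + a * mB + sqrt(1 - v) * stats::rnorm(n)
  samples <- sprintf("S%03d", seq_len(n))
  genes <- c("GENEA", "GENEB")
  meth <- rbind(mA, mB)
  expr <- rbind(eA, eB)
  if (spec$n_background > 0L) {
    bg <- sprintf("BG%02d", seq_len(spec$n_background))
    for (g in bg) {
      mg <- l * M + s * stats::rnorm(n)
      eg <- a * mg + sqrt(1 - a^2) * stats::rnorm(n)
      meth <- rbind(meth, mg)
      expr <- rbind(expr, eg)
    }
    genes <- c(genes, bg)
  }
  meth <- meth + spec$noise_sd * matrix(stats::rnorm(length(meth)), nrow(meth))
  expr <- expr + spec$noise_sd * matrix(stats::rnorm(length(expr)), nrow(expr))
  dimnames(meth) <- dimnames(expr) <- list(genes, samples)
  graph <- pathway_graph(
    nodes = data.frame(name = c("GENEA", "GENEB"), type = c("protein", "protein")),
    edges = data.frame(from = "GENEA", to = "GENEB", type = "inhibits",
                       track = "toy_pathway")
  )
  list(methylation = omics_matrix(meth, "methylation", "continuous"),
       expression = omics_matrix(expr, "expression", "continuous"),
       graph = graph, spec = spec)
}

#' Specification of the hypermutated-cohort data set
#'
#' Emulates a colorectal-carcinoma-like tumor cohort in which a minority
#' subgroup carries an elevated somatic mutation burden ("hypermutated")
#' and a designated driver gene (default BRAF) is preferentially mutated
#' within it. Emitted platforms: a binary somatic-mutation matrix,
#' continuous copy-number and expression matrices with gene-wise coupling
#' (`expr = rho_cn_expr * cn + noise`), and a continuous inferred-activity
#' matrix loading on expression (plus a bump for mutated driver samples),
#' standing in for pathway-inference output consumed as just another
#' matrix. A phenotype annotation labels every sample hypermutated or
#' non-hypermutated, and a small typed pathway graph (including an
#' inhibitory edge and a complex node) connects the genes.
#'
#' @param n_genes number of genes (3..9 drawn from a fixed CRC-flavored
#'   symbol list headed by BRAF, APC, CTNNB1; more get synthetic symbols).
#' @param n_samples cohort size.
#' @param fraction_hypermutated fraction of samples in the hypermutated
#'   group, in `(0, 1)`; must give at least one sample.
#' @param mut_rate_hyper,mut_rate_nonhyper driver-gene mutation probability
#'   per group; `mut_rate_hyper > mut_rate_nonhyper`.
#' @param bg_rate_hyper,bg_rate_nonhyper mutation probability of the
#'   non-driver genes per group (elevated in the hypermutated group — that
#'   is what hypermutation means).
#' @param rho_cn_expr copy-number-to-expression coupling.
#' @param rho_expr_act expression-to-activity coupling.
#' @param driver activity bump added to mutated driver samples is fixed at
#'   1; `driver` names the driver gene.
#' @param seed integer seed.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes = 9L, n_samples = 200L, fraction_hypermutated = 0.15,
                        mut_rate_hyper = 0.6, mut_rate_nonhyper = 0.05,
                        bg_rate_hyper = 0.2, bg_rate_nonhyper = 0.03,
                        rho_cn_expr = 0.5, rho_expr_act = 0.7,
                        driver = "BRAF", seed = 1L) {
  rates <- c(mut_rate_hyper, mut_rate_nonhyper, bg_rate_hyper, bg_rate_nonhyper)
  if (any(rates < 0 | rates > 1)) stop("mutation rates must lie in [0, 1]", call. = FALSE)
  if (mut_rate_hyper <= mut_rate_nonhyper)
    stop("mut_rate_hyper must exceed mut_rate_nonhyper for the driver gene", call. = FALSE)
  if (fraction_hypermutated <= 0 || fraction_hypermutated >= 1)
    stop("fraction_hypermutated must lie in (0, 1)", call. = FALSE)
  if (fraction_hypermutated * n_samples < 1)
    stop("fraction_hypermutated * n_samples < 1: no hypermutated samples", call. = FALSE)
  if (n_genes < 3L) stop("n_genes must be >= 3", call. = FALSE)
  genes <- .cohort_genes(n_genes)
  if (!driver %in% genes)
    stop("driver gene '", driver, "' is not among the cohort genes", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
                 fraction_hypermutated = fraction_hypermutated,
                 mut_rate_hyper = mut_rate_hyper, mut_rate_nonhyper = mut_rate_nonhyper,
                 bg_rate_hyper = bg_rate_hyper, bg_rate_nonhyper = bg_rate_nonhyper,
                 rho_cn_expr = rho_cn_expr, rho_expr_act = rho_expr_act,
                 driver = driver, seed = as.integer(seed)),
            class = "cohort_spec")
}

.cohort_genes <- function(n) {
  base <- c("BRAF", "APC", "CTNNB1", "MYC", "KRAS", "PIK3CA", "TP53", "SMAD4", "TGFBR2")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("GENE%02d", seq_len(n - length(base))))
}

#' Generate the hypermutated-cohort data set
#'
#' @param spec a [cohort_spec].
#' @return list with elements `matrices` (named list of [omics_matrix]:
#'   `mutation`, `copynumber`, `expression`, `activity`), `annotation`
#'   (the hypermutated/non-hypermutated [sample_annotation]), `graph`
#'   (typed [pathway_graph]), `genes` (a [gene_set]) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  genes <- .cohort_genes(spec$n_genes)
  samples <- sprintf("TCGA%04d", seq_len(n))
  n_h <- max(1L, round(spec$fraction_hypermutated * n))
  hyper <- samples %in% sample(samples, n_h)
  mut <- matrix(0, length(genes), n, dimnames = list(genes, samples))
  for (g in genes) {
    p <- if (g == spec$driver) {
      ifelse(hyper, spec$mut_rate_hyper, spec$mut_rate_nonhyper)
    } else {
      ifelse(hyper, spec$bg_rate_hyper, spec$bg_rate_nonhyper)
    }
    mut[g, ] <- stats::rbinom(n, 1L, p)
  }
  cn <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
               dimnames = list(genes, samples))
  r1 <- spec$rho_cn_expr
  expr <- r1 * cn + sqrt(1 - r1^2) *
    matrix(stats::rnorm(length(genes) * n), length(genes), n)
  r2 <- spec$rho_expr_act
  act <- r2 * expr + sqrt(1 - r2^2) *
    matrix(stats::rnorm(length(genes) * n), length(genes), n)
  act[spec$driver, ] <- act[spec$driver, ] + mut[spec$driver, ]
  dimnames(expr) <- dimnames(act) <- list(genes, samples)
  annotation <- sample_annotation(
    stats::setNames(ifelse(hyper, "hypermutated", "non-hypermutated"), samples),
    "hypermutated"
  )
  list(matrices = list(
         mutation = omics_matrix(mut, "mutation", "binary"),
         copynumber = omics_matrix(cn, "copynumber", "continuous"),
         expression = omics_matrix(expr, "expression", "continuous"),
         activity = omics_matrix(act, "activity", "continuous")),
       annotation = annotation,
       graph = .cohort_graph(genes),
       genes = gene_set(genes, "cohort_pathway"),
       spec = spec)
}

# small CRC-flavored typed pathway over whichever template genes are
# present; always includes the APC -| CTNNB1 inhibition and a complex node
.cohort_graph <- function(genes) {
  nodes <- data.frame(name = genes, type = rep("protein", length(genes)))
  nodes <- rbind(nodes, data.frame(name = "TCF_COMPLEX", type = "complex"))
  template <- list(
    c("APC", "CTNNB1", "inhibits"),
    c("CTNNB1", "TCF_COMPLEX", "component"),
    c("TCF_COMPLEX", "MYC", "activates"),
    c("KRAS", "BRAF", "activates"),
    c("BRAF", "MYC", "activates"),
    c("KRAS", "PIK3CA", "activates"),
    c("TGFBR2", "SMAD4", "activates"),
    c("SMAD4", "MYC", "inhibits"),
    c("TP53", "MYC", "undirected")
  )
  keep <- vapply(template, function(e) {
    all(c(e[1L], e[2L]) %in% nodes$name)
  }, logical(1L))
  template <- template[keep]
  edges <- data.frame(
    from = vapply(template, `[`, character(1L), 1L),
    to = vapply(template, `[`, character(1L), 2L),
    type = vapply(template, `[`, character(1L), 3L),
    track = "crc_pathway"
  )
  pathway_graph(nodes, edges)
}

#' Write a generated data set into a directory of standard files
#'
#' `write_toy_fixtures` writes `methylation.tsv`, `expression.tsv`,
#' `pathway.tsv` (typed dialect) and `genes.txt`; `write_cohort_fixtures`
#' writes one TSV per platform plus `hypermutated.tsv`, `pathway.tsv` and
#' `genes.txt`. Everything round-trips through the package readers.
#'
#' @param toy result of [generate_toy].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_toy_fixtures <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(toy$methylation, file.path(dir, "methylation.tsv"))
  write_matrix(toy$expression, file.path(dir, "expression.tsv"))
  write_network_typed(toy$graph, file.path(dir, "pathway.tsv"))
  write_gene_set(gene_set(c("GENEA", "GENEB"), "toy"), file.path(dir, "genes.txt"))
  invisible(dir)
}

#' @rdname write_toy_fixtures
#' @param cohort result of [generate_cohort].
#' @export
write_cohort_fixtures <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in cohort$matrices)
    write_matrix(m, file.path(dir, paste0(m$platform, ".tsv")))
  write_annotation(cohort$annotation, file.path(dir, "hypermutated.tsv"))
  write_network_typed(cohort$graph, file.path(dir, "pathway.tsv"))
  write_gene_set(cohort$genes, file.path(dir, "genes.txt"))
  invisible(dir)
}
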