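# Delimited-text readers/writers and the synthetic fixture generator.
# Dialect: tab-separated, UTF-8, '.' decimal, mandatory header row,
# first column the sample id.

read_one_table <- function(path, what) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop(sprintf("%s ('%s'): expected a sample-id column plus data",
                 what, path))
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop(sprintf("%s ('%s'): duplicated sample ids: %s", what, path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1L, drop = FALSE],
                                              2L, as.numeric))) &
                   !is.na(as.matrix(tab[, -1L, drop = FALSE])),
                 arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("%s ('%s'): non-numeric value at row %d, column '%s'",
                   what, path, bad[1L, 1L],
                   colnames(tab)[-1L][bad[1L, 2L]]))
    m <- apply(tab[, -1L, drop = FALSE], 2L, as.numeric)
  }
  rownames(m) <- ids
  m
}

#' Read aligned expression/genotype/phenotype tables
#'
#' Reads tab-separated tables (header row, first column the sample id),
#' inner-joins them on sample id (order taken from the expression table)
#' and drops samples with any missing value across the used tables — the
#' completeness filter applied before inference.
#'
#' @param expression path to the expression table (mandatory).
#' @param genotypes,phenotypes,covariates optional table paths.
#' @param quiet suppress the join/filter summary message.
#' @return a [net_dataset()].
#' @export
read_tables <- function(expression, genotypes = NULL, phenotypes = NULL,
                        covariates = NULL, quiet = FALSE) {
  tabs <- list(expression = read_one_table(expression, "expression"))
  if (!is.null(genotypes))
    tabs$genotypes <- read_one_table(genotypes, "genotypes")
  if (!is.null(phenotypes))
    tabs$phenotypes <- read_one_table(phenotypes, "phenotypes")
  if (!is.null(covariates))
    tabs$covariates <- read_one_table(covariates, "covariates")
  n_seen <- max(vapply(tabs, nrow, integer(1)))
  ids <- Reduce(intersect, lapply(tabs, rownames))
  if (length(ids) == 0)
    stop("no samples shared across the input tables")
  ids <- rownames(tabs$expression)[rownames(tabs$expression) %in% ids]
  tabs <- lapply(tabs, function(m) m[ids, , drop = FALSE])
  complete <- Reduce(`&`, lapply(tabs, function(m) rowSums(is.na(m)) == 0))
  tabs <- lapply(tabs, function(m) m[complete, , drop = FALSE])
  if (!quiet)
    message(sprintf(
      "read_tables: %d samples kept (%d dropped by join/completeness filter)",
      sum(complete), n_seen - sum(complete)))
  net_dataset(tabs$expression, tabs$genotypes, tabs$phenotypes,
              tabs$covariates, sample_ids = rownames(tabs$expression))
}

#' Specification of a synthetic eQTL-study fixture
#'
#' Describes a synthetic data layout mirroring an F2-cross eQTL study:
#' expression traits sampled from a random moralized network, biallelic
#' marker dosages, downstream phenotypes built as sparse linear
#' combinations of features, a binary sex-like covariate, and optional
#' latent confounders loading on both expression and phenotypes (what
#' the PC covariates are meant to absorb).
#'
#' @param n samples; `p_expr` expression traits; `m` markers; `q`
#'   phenotypes.
#' @param planted list (one element per phenotype, recycled) of lists
#'   `list(features = <ids into the combined expression+marker set>,
#'   effects = <sizes in residual-sd units>)`.
#' @param maf minor allele frequency for the `Binomial(2, maf)` dosages
#'   (0.5 for an F2 intercross).
#' @param edge_prob expression-network directed edge probability.
#' @param n_confounders,confounder_sd latent factor count and strength.
#' @param sex_effect additive phenotype effect of the binary covariate.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n = 300, p_expr = 100, m = 20, q = 2,
                         planted = list(list(features = integer(0),
                                             effects = numeric(0))),
                         maf = 0.5, edge_prob = 1 / p_expr,
                         n_confounders = 0, confounder_sd = 1,
                         sex_effect = 0) {
  spec <- structure(as.list(environment()), class = "fixture_spec")
  for (pl in spec$planted)
    if (any(pl$features < 1 | pl$features > p_expr + m))
      stop("planted feature id outside the expression+marker range")
  spec
}

#' Generate a synthetic fixture on disk
#'
#' Samples the dataset described by a [fixture_spec()] and, if `dir` is
#' given, writes `expression.tsv`, `genotypes.tsv`, `phenotypes.tsv`,
#' `covariates.tsv` plus the ground truth (`truth_effects.tsv`,
#' `truth_edges.tsv`) alongside.  All data are synthetic; no real study
#' data are involved.
#'
#' @param spec a [fixture_spec()].
#' @param seed integer seed (byte-identical files for identical seeds).
#' @param dir optional output directory.
#' @return invisibly, a list with the [net_dataset()], the truth tables
#'   and the written paths.
#' @export
generate_fixture <- function(spec, seed, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  seeds <- spawn_seeds(seed, 5L)
  net <- simulate_network(spec$p_expr, spec$n, spec$edge_prob, seeds[1L])
  expr <- net$Y
  geno <- with_seed(seeds[2L],
                    matrix(rbinom(spec$n * spec$m, 2L, spec$maf),
                           spec$n, spec$m))
  sex <- with_seed(seeds[3L], rbinom(spec$n, 1L, 0.5))
  conf <- NULL
  if (spec$n_confounders > 0) {
    conf <- with_seed(seeds[4L],
                      matrix(rnorm(spec$n * spec$n_confounders),
                             spec$n, spec$n_confounders))
    load <- with_seed((seeds[4L] %% MAX_SEED) + 1L,
                      matrix(rnorm(spec$n_confounders * spec$p_expr,
                                   sd = spec$confounder_sd),
                             spec$n_confounders, spec$p_expr))
    expr <- expr + conf %*% load
  }
  feat <- cbind(expr, geno)
  feat_names <- c(paste0("expr", seq_len(spec$p_expr)),
                  paste0("marker", seq_len(spec$m)))
  colnames(feat) <- feat_names
  planted <- rep(spec$planted, length.out = spec$q)
  pheno <- matrix(NA_real_, spec$n, spec$q)
  truth <- NULL
  noise_seeds <- spawn_seeds(seeds[5L], spec$q)
  for (qq in seq_len(spec$q)) {
    pl <- planted[[qq]]
    mu <- rep(0, spec$n)
    if (length(pl$features)) {
      # effect sizes are in residual-sd units (residual sd is 1)
      bet <- pl$effects / apply(feat[, pl$features, drop = FALSE], 2L, sd)
      mu <- drop(feat[, pl$features, drop = FALSE] %*% bet)
      truth <- rbind(truth, data.frame(
        phenotype = paste0("pheno", qq),
        feature = feat_names[pl$features],
        effect_sd_units = pl$effects))
    }
    if (spec$n_confounders > 0)
      mu <- mu + drop(conf %*% rep(spec$confounder_sd,
                                   spec$n_confounders))
    mu <- mu + spec$sex_effect * sex
    pheno[, qq] <- mu + with_seed(noise_seeds[qq], rnorm(spec$n))
  }
  colnames(expr) <- feat_names[seq_len(spec$p_expr)]
  colnames(geno) <- feat_names[spec$p_expr + seq_len(spec$m)]
  colnames(pheno) <- paste0("pheno", seq_len(spec$q))
  covar <- matrix(sex, ncol = 1L, dimnames = list(NULL, "sex"))
  ids <- sprintf("s%03d", seq_len(spec$n))
  rownames(expr) <- rownames(geno) <- rownames(pheno) <-
    rownames(covar) <- ids
  ds <- net_dataset(expr, geno, pheno, covar, sample_ids = ids)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(m, f) {
      out <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
      write.table(out, file.path(dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      file.path(dir, f)
    }
    paths <- c(wt(expr, "expression.tsv"), wt(geno, "genotypes.tsv"),
               wt(pheno, "phenotypes.tsv"), wt(covar, "covariates.tsv"))
    tf <- file.path(dir, "truth_effects.tsv")
    write.table(truth %||% data.frame(phenotype = character(0),
                                      feature = character(0),
                                      effect_sd_units = numeric(0)),
                tf, sep = "\t", quote = FALSE, row.names = FALSE)
    ef <- file.path(dir, "truth_edges.tsv")
    write.table(data.frame(i = net$edges[, 1L], j = net$edges[, 2L]),
                ef, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, tf, ef)
  }
  invisible(list(dataset = ds, truth_effects = truth,
                 truth_edges = net$edges, network = net, paths = paths))
}

#' Write a network graph
#'
#' Formats: `"edge-tsv"` (lossless; round-trips through [read_graph()]),
#' `"graphml"` (with node role and edge provenance attributes) and
#' `"sif"` (relation token `nd`, non-directed).
#'
#' @param graph a `net_graph` from [build_union_graph()].
#' @param path output file.
#' @param format one of `"edge-tsv"`, `"graphml"`, `"sif"`.
#' @return invisibly, the path.
#' @export
write_graph <- function(graph, path, format = c("edge-tsv", "graphml",
                                                "sif")) {
  format <- match.arg(format)
  e <- graph$edges
  if (format == "edge-tsv") {
    write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    lines <- if (nrow(e)) sprintf("%s\tnd\t%s", e$node_a, e$node_b)
      else character(0)
    writeLines(lines, path)
  } else {
    v <- graph$vertices
    xml <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="role" for="node" attr.name="role" attr.type="string"/>',
      '  <key id="score" for="edge" attr.name="p_sym" attr.type="double"/>',
      '  <key id="prov" for="edge" attr.name="provenance" attr.type="string"/>',
      '  <graph id="G" edgedefault="undirected">',
      if (nrow(v)) sprintf(
        '    <node id="%s"><data key="role">%s</data></node>',
        v$id, v$role),
      if (nrow(e)) sprintf(
        paste0('    <edge source="%s" target="%s">',
               '<data key="score">%.17g</data>',
               '<data key="prov">%s</data></edge>'),
        e$node_a, e$node_b, e$p_sym, e$provenance),
      '  </graph>', '</graphml>')
    writeLines(xml, path)
  }
  invisible(path)
}

#' Read a graph written as edge TSV
#'
#' @param path an `"edge-tsv"` file from [write_graph()].
#' @param threshold threshold annotation to attach.
#' @return a `net_graph`.
#' @export
read_graph <- function(path, threshold = NA_real_) {
  e <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(e) == 0)
    e <- data.frame(node_a = character(0), node_b = character(0),
                    role_a = character(0), role_b = character(0),
                    p_sym = numeric(0), provenance = character(0))
  vid <- c(e$node_a, e$node_b)
  vrole <- c(e$role_a, e$role_b)
  first <- !duplicated(vid)
  v <- data.frame(id = vid[first], role = vrole[first])
  v <- v[order(v$id), ]
  rownames(v) <- NULL
  structure(list(vertices = v, edges = e, threshold = threshold),
            class = "net_graph")
}
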