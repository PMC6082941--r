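#' Run the full panel analysis workflow
#'
#' Orchestrates the analysis stages in dependency order — forensic summary,
#' Hardy-Weinberg and LD screens, pairwise distances, neighbor-joining tree,
#' MDS ordination, admixture clustering — writing plain-text outputs (TSV,
#' PHYLIP, Newick) plus a machine-readable JSON manifest of inputs,
#' parameters, seeds and files produced. A rerun with the same inputs and
#' seeds reproduces the stochastic-stage outputs byte for byte. Any stage
#' failure halts the run with the stage name; files already written are
#' flagged in the error.
#'
#' Stages needing several populations (`distance`, `tree`, `mds`) require
#' the genotype matrix to contain them (`tree` needs >= 3).
#'
#' @param gm a [genotype_matrix()] or a path readable by
#'   [read_genotype_table()]
#' @param out_dir output directory (created if absent)
#' @param stages subset of `c("summary", "hwe", "ld", "distance", "tree",
#'   "mds", "structure")`
#' @param alpha family-wise significance level for HWE / differentiation
#' @param r2_threshold LD screen cutoff
#' @param distance_metric metric for the distance/tree/mds stages
#' @param K vector of cluster numbers for the structure stage
#' @param burn_in,reps Gibbs sampler lengths
#' @param seed RNG seed for all stochastic stages (required if `structure`
#'   is enabled)
#' @param dialect dialect for reading `gm` when it is a path
#' @return the manifest, invisibly (also written to `manifest.json`)
#' @export
run_pipeline <- function(gm, out_dir,
                         stages = c("summary", "hwe", "ld", "distance",
                                    "tree", "mds", "structure"),
                         alpha = 0.05, r2_threshold = 0.8,
                         distance_metric = c("da", "fst"),
                         K = 2:7, burn_in = 10000, reps = 10000,
                         seed = NULL, dialect = "csv") {
  stages <- match.arg(stages, several.ok = TRUE)
  distance_metric <- match.arg(distance_metric)
  input_path <- NULL
  if (is.character(gm)) {
    input_path <- gm
    gm <- read_genotype_table(gm, dialect = dialect)
  }
  if ("structure" %in% stages && is.null(seed))
    stop("the structure stage requires a seed")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  files <- character()
  manifest <- list(
    package_version = as.character(utils::packageVersion("indelpanel")),
    input = if (is.null(input_path)) "in-memory genotype_matrix"
            else input_path,
    n_samples = n_samples(gm), n_loci = n_loci(gm),
    populations = as.list(table(gm$populations)),
    parameters = list(alpha = alpha, r2_threshold = r2_threshold,
                      distance_metric = distance_metric, K = K,
                      burn_in = burn_in, reps = reps, seed = seed),
    stages = list())
  emit <- function(name, df) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
    path
  }
  run_stage <- function(name, fn) {
    message("[indelpanel] stage ", name,
            " (alpha=", alpha, ", r2=", r2_threshold,
            if (!is.null(seed)) paste0(", seed=", seed), ")")
    out <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (files already written: ",
           paste(basename(files), collapse = ", "), ")", call. = FALSE))
    manifest$stages[[name]] <<- out
    out
  }
  dm <- NULL
  if ("summary" %in% stages) run_stage("summary", function() {
    prof <- profile_table(gm)
    path <- emit("summary.tsv", as.data.frame(prof))
    list(file = path, CMP = attr(prof, "CMP"), CPE = attr(prof, "CPE"))
  })
  if ("hwe" %in% stages) run_stage("hwe", function() {
    tab <- hwe_table(gm, alpha = alpha)
    list(file = emit("hwe.tsv", tab),
         bonferroni_threshold = attr(tab, "bonferroni_threshold"),
         n_significant = sum(tab$significant_after_bonferroni))
  })
  if ("ld" %in% stages) run_stage("ld", function() {
    tab <- ld_screen(gm, r2_threshold = r2_threshold)
    list(file = emit("ld.tsv", tab), n_pairs = nrow(tab),
         n_above_threshold = sum(tab$above_threshold, na.rm = TRUE))
  })
  if (any(c("distance", "tree", "mds") %in% stages)) {
    dm <- distance_matrix(gm, metric = distance_metric)
  }
  if ("distance" %in% stages) run_stage("distance", function() {
    tsv <- emit(paste0("distance_", distance_metric, ".tsv"),
                data.frame(population = rownames(dm),
                           as.data.frame(unclass(dm), check.names = FALSE)))
    phy <- file.path(out_dir, paste0("distance_", distance_metric,
                                     ".phylip"))
    write_phylip_distance(dm, phy)
    files <<- c(files, phy)
    list(files = c(tsv, phy), metric = distance_metric)
  })
  if ("tree" %in% stages) run_stage("tree", function() {
    tr <- neighbor_joining(dm)
    path <- file.path(out_dir, "tree.nwk")
    write_newick(tr, path)
    files <<- c(files, path)
    list(file = path, n_leaves = length(tr$tip.label))
  })
  if ("mds" %in% stages) run_stage("mds", function() {
    fit <- classical_mds(dm, n_dims = min(2, nrow(dm) - 1))
    path <- emit("mds.tsv",
                 data.frame(population = rownames(fit$coords),
                            as.data.frame(fit$coords)))
    list(file = path, eigenvalues = fit$eigenvalues)
  })
  if ("structure" %in% stages) run_stage("structure", function() {
    out <- list()
    for (k in K) {
      fit <- structure_fit(gm, K = k, burn_in = burn_in, reps = reps,
                           seed = seed + k)
      path <- emit(sprintf("structure_K%d.tsv", k),
                   data.frame(sample_id = rownames(fit$Q),
                              population = fit$populations,
                              as.data.frame(fit$Q)))
      out[[paste0("K", k)]] <- list(file = path, seed = seed + k,
                                    final_loglik =
                                      utils::tail(fit$loglik_trace$loglik, 1))
    }
    out
  })
  manifest$files <- files
  manifest$wall_clock_sec <-
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
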