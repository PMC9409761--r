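#' Write a result tibble as TSV with a commented metadata header
#'
#' Lines prefixed `#` carry run metadata (stage, package version, seed,
#' timestamp-free so reruns are byte-identical); numeric columns may be
#' rounded for presentation.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param meta Named list written as `# key: value` lines.
#' @param round Optional number of decimal places for numeric columns
#'   (`NULL` = full precision).
#' @return `x`, invisibly.
#' @export
write_result_tsv <- function(x, path, meta = list(), round = NULL) {
  if (!is.null(round)) {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], base::round, digits = round)
  }
  header <- vapply(names(meta),
                   function(k) paste0("# ", k, ": ", meta[[k]]),
                   character(1))
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(x)
}

#' Run the full divergence pipeline
#'
#' Orchestrates every stage on one trial (and optionally one qualitative
#' table): per-trait augmented ANOVA, genetic variability parameters,
#' descriptive statistics, Shannon-Weaver diversity, correlations, PCA,
#' hierarchical clustering with cluster means, and MGIDI with selection
#' differentials.  One TSV per result table is written to `out_dir`, each
#' with a `#` metadata header, plus a `manifest.yaml` recording the
#' configuration, so an identical call reproduces identical bytes.  Any
#' stage failure aborts with the stage name and removes partial outputs.
#'
#' @param trial An [augmented_trial()].
#' @param qualitative Optional [qualitative_table()].
#' @param out_dir Output directory (created if needed).
#' @param k Selection-intensity constant for genetic advance.
#' @param clusters Number of genotype clusters.
#' @param linkage Clustering linkage.
#' @param intensity MGIDI selected fraction.
#' @param goals Trait goals for MGIDI; default: the trial's trait
#'   dictionary.
#' @param seed Seed recorded in output headers (the pipeline itself is
#'   deterministic).
#' @param round Presentation rounding for TSVs (`NULL` = full precision).
#' @return Invisibly, a named list of the result objects.
#' @examples
#' \donttest{
#' fx <- landrace_fixture(seed = 1)
#' out <- run_pipeline(fx$trial, fx$qualitative, out_dir = tempfile())
#' }
#' @export
run_pipeline <- function(trial, qualitative = NULL, out_dir,
                         k = 2.063, clusters = 6,
                         linkage = c("complete", "average", "ward"),
                         intensity = 0.20, goals = NULL, seed = NULL,
                         round = NULL) {
  stopifnot(inherits(trial, "augmented_trial"))
  linkage <- match.arg(linkage)
  goals <- goals %||% trial$traits
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- "setup"
  on_fail <- function(e) {
    unlink(written)
    abort(paste0("pipeline failed at stage ", stage, ": ",
                 conditionMessage(e)),
          class = "phenodiv_pipeline_error")
  }
  meta <- list(package = paste0("phenodiv ",
                                as.character(utils::packageVersion("phenodiv"))),
               seed = seed %||% "none",
               n_blocks = length(trial$blocks),
               n_checks = length(trial$checks),
               n_tests = length(trial$tests))
  emit <- function(x, name, stage_meta = list()) {
    path <- file.path(out_dir, name)
    write_result_tsv(x, path, meta = c(list(stage = stage), meta,
                                       stage_meta), round = round)
    written <<- c(written, path)
  }

  results <- withCallingHandlers(
    tryCatch({
      stage <- "anova"
      anova_tbl <- anova_table_all(trial)
      emit(anova_tbl, "anova.tsv")

      stage <- "adjusted_means"
      means <- adjusted_means(trial)
      emit(means, "adjusted_means.tsv")

      stage <- "variability"
      variability <- genetic_variability(trial, k = k)
      emit(variability, "variability.tsv", list(k = k))
      descriptives <- descriptive_stats(means, trial$traits$abbr)
      emit(descriptives, "descriptives.tsv")

      stage <- "diversity"
      diversity <- NULL
      if (!is.null(qualitative)) {
        diversity <- diversity_profile(qualitative)
        emit(as_tibble(diversity), "diversity.tsv",
             list(mean_h_norm = attr(diversity, "mean_h_norm")))
      }

      stage <- "correlation"
      correlations <- trait_correlations(means, trial$traits$abbr)
      emit(tidy(correlations), "correlation.tsv")

      stage <- "pca"
      pca <- trait_pca(means, trial$traits$abbr)
      emit(tidy(pca, "eigenvalues"), "pca_eigen.tsv")
      emit(tidy(pca, "loadings"), "pca_loadings.tsv")
      emit(tidy(pca, "scores"), "pca_scores.tsv")

      stage <- "clustering"
      clustering <- cluster_genotypes(means, k = clusters,
                                      linkage = linkage,
                                      traits = trial$traits$abbr)
      emit(clustering$assignments, "clusters.tsv",
           list(linkage = linkage, k_clusters = clusters))
      emit(clustering$cluster_means, "cluster_means.tsv")

      stage <- "mgidi"
      mg <- mgidi(means, goals = goals, intensity = intensity,
                  traits = trial$traits$abbr)
      emit(mg$index, "mgidi_ranking.tsv", list(intensity = intensity))
      emit(as_tibble(mg$factor_model$loadings, rownames = "trait"),
           "factor_loadings.tsv")
      emit(as_tibble(mg$contributions, rownames = "genotype"),
           "contributions.tsv")
      h2v <- setNames(variability$h2, variability$trait)
      emit(selection_differentials(mg, h2 = h2v),
           "selection_differential.tsv")

      stage <- "manifest"
      manifest <- list(
        package = meta$package,
        seed = meta$seed,
        config = list(k = k, clusters = clusters, linkage = linkage,
                      intensity = intensity,
                      round = round %||% "full precision"),
        design = list(blocks = length(trial$blocks),
                      checks = length(trial$checks),
                      tests = length(trial$tests),
                      traits = trial$traits$abbr),
        outputs = basename(written)
      )
      yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

      list(anova = anova_tbl, means = means, variability = variability,
           descriptives = descriptives, diversity = diversity,
           correlations = correlations, pca = pca,
           clustering = clustering, mgidi = mg)
    }, error = on_fail),
    warning = function(w) invokeRestart("muffleWarning"))
  invisible(results)
}
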