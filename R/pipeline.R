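#' Pipeline run configuration
#'
#' One object carrying the seed, the stage list and every module threshold,
#' serialized verbatim into the run report for reproducibility.
#'
#' @param seed Top-level seed; each stage derives its own stream.
#' @param stages Stages to run, in dependency order.
#' @param generator A [generator_config()] (its seed is overridden by
#'   `seed`).
#' @param evalue_max Identification E-value threshold.
#' @param presence_threshold Motif presence threshold.
#' @param n_shuffles Permutations for the E-value null.
#' @param k_subfamilies Number of subfamilies to cut.
#' @param bootstrap_reps Bootstrap replicates.
#' @param identity_min Minimum sister-pair identity.
#' @param tandem_window_bp,tandem_max_genes Tandem rule parameters.
#' @param fpkm_threshold Expressed-tissue FPKM threshold.
#' @param pseudocount Normalization pseudocount.
#' @param alpha,fold_min qPCR calling parameters.
#' @return A list of class `famscan_run_config`.
#' @export
run_config <- function(seed = 42,
                       stages = c("simulate", "identify", "props", "phylo",
                                  "structure", "duplication", "expression",
                                  "qpcr"),
                       generator = generator_config(seed = seed),
                       evalue_max = 0.1, presence_threshold = 0.8,
                       n_shuffles = 999, k_subfamilies = 5,
                       bootstrap_reps = 100, identity_min = 0.98,
                       tandem_window_bp = 1e5, tandem_max_genes = 5,
                       fpkm_threshold = 1, pseudocount = 0.01,
                       alpha = 0.05, fold_min = 2) {
  generator$seed <- seed
  structure(as.list(environment()), class = "famscan_run_config")
}

stage_output <- function(state, stage, needed_by) {
  if (is.null(state[[stage]]))
    stop(sprintf("stage '%s' is disabled but '%s' requires its output",
                 stage, needed_by), call. = FALSE)
  state[[stage]]
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order on the synthetic bundle:
#' simulate, identify, props, phylo, structure, duplication, expression,
#' qpcr. Randomness flows from `config$seed` through per-stage derived
#' seeds, so rerunning an identical configuration reproduces every
#' headline number.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory; when given, the simulated
#'   inputs and the report (JSON + TSV) are written there.
#' @return A list of class `famscan_report` with per-stage results and a
#'   `headline` summary.
#' @export
run_all <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "famscan_run_config"))
  state <- list()
  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(NULL)
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  state$simulate <- run_stage("simulate", function() {
    bundle <- simulate_genome(config$generator)
    list(bundle = bundle,
         expression = simulate_expression(bundle),
         ct = simulate_ct(bundle))
  })

  state$identify <- run_stage("identify", function() {
    sim <- stage_output(state, "simulate", "identify")
    bundle <- sim$bundle
    identify_family(
      bundle$proteins[, c("protein_id", "sequence")],
      motifs = hsp70_motifs(),
      annotation = bundle$genes[, c("gene_id", "chromosome",
                                    "start", "end")],
      evalue_max = config$evalue_max,
      presence_threshold = config$presence_threshold,
      n_shuffles = config$n_shuffles,
      seed = derive_seed(config$seed, "evalue"))
  })

  accepted_proteins <- function(caller) {
    idf <- stage_output(state, "identify", caller)
    idf[idf$verdict == "accept", c("protein_id", "sequence")]
  }

  state$props <- run_stage("props", function() {
    protein_properties(accepted_proteins("props"))
  })

  state$phylo <- run_stage("phylo", function() {
    acc <- accepted_proteins("phylo")
    tree <- bootstrap_supports(acc, n_reps = config$bootstrap_reps,
                               seed = derive_seed(config$seed, "bootstrap"))
    subfam <- cut_subfamilies(tree, config$k_subfamilies)
    sisters <- sister_pairs(tree, acc, identity_min = config$identity_min)
    list(tree = tree, subfamilies = subfam, sisters = sisters)
  })

  state$structure <- run_stage("structure", function() {
    sim <- stage_output(state, "simulate", "structure")
    acc <- accepted_proteins("structure")
    genes <- sim$bundle$genes
    fam <- genes[genes$gene_id %in% acc$protein_id, ]
    list(structure = structure_report(fam),
         chromosomes = chromosome_distribution(fam),
         motif_presence = motif_presence_matrix(
           acc, threshold = config$presence_threshold))
  })

  state$duplication <- run_stage("duplication", function() {
    sim <- stage_output(state, "simulate", "duplication")
    ph <- stage_output(state, "phylo", "duplication")
    classify_pairs(ph$sisters,
                   sim$bundle$genes[, c("gene_id", "chromosome", "start")],
                   proteins = sim$bundle$proteins,
                   window_bp = config$tandem_window_bp,
                   max_intervening = config$tandem_max_genes)
  })

  state$expression <- run_stage("expression", function() {
    sim <- stage_output(state, "simulate", "expression")
    normalized <- normalize_expression(sim$expression,
                                       pseudocount = config$pseudocount)
    list(normalized = normalized,
         dendrogram = hcluster_expression(normalized),
         tissue_counts = expressed_tissue_counts(
           sim$expression, threshold = config$fpkm_threshold))
  })

  state$qpcr <- run_stage("qpcr", function() {
    sim <- stage_output(state, "simulate", "qpcr")
    regulation_calls(sim$ct, alpha = config$alpha,
                     fold_min = config$fold_min)
  })

  headline <- report_headline(state, config)
  report <- structure(c(state, list(headline = headline, config = config)),
                      class = "famscan_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

report_headline <- function(state, config) {
  h <- list(seed = config$seed)
  if (!is.null(state$identify)) {
    h$raw_candidates <- sum(state$identify$raw_candidate)
    h$accepted <- sum(state$identify$verdict == "accept")
  }
  if (!is.null(state$phylo)) {
    sizes <- sort(table(state$phylo$subfamilies$subfamily),
                  decreasing = TRUE)
    h$subfamily_sizes <- paste(as.integer(sizes), collapse = "/")
    h$sister_pairs <- nrow(state$phylo$sisters)
  }
  if (!is.null(state$duplication)) {
    h$tandem <- sum(state$duplication$class == "tandem")
    h$segmental <- sum(state$duplication$class == "segmental")
  }
  if (!is.null(state$qpcr)) {
    ab <- hsp70_treatments()$abiotic
    calls <- state$qpcr
    up_all_abiotic <- calls |>
      dplyr::filter(.data$treatment %in% ab, .data$call == "up") |>
      dplyr::count(.data$gene_id) |>
      dplyr::filter(.data$n == length(ab)) |>
      nrow()
    h$up_all_abiotic <- up_all_abiotic
    h$changed_sa <- sum(calls$treatment == "SA" & calls$call != "unchanged")
  }
  tibble::as_tibble(h)
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- report$simulate
  if (!is.null(sim)) {
    write_genome_files(sim$bundle, outdir, expression = sim$expression,
                       ct = sim$ct)
  }
  readr::write_tsv(report$headline, file.path(outdir, "headline.tsv"))
  cfg <- report$config
  cfg$generator <- unclass(cfg$generator)
  jsonlite::write_json(
    list(headline = report$headline, config = unclass(cfg)),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  if (!is.null(report$phylo)) {
    ape::write.tree(report$phylo$tree, file.path(outdir, "tree.nwk"))
    readr::write_tsv(report$phylo$subfamilies,
                     file.path(outdir, "subfamilies.tsv"))
  }
  if (!is.null(report$identify)) {
    readr::write_tsv(dplyr::select(tibble::as_tibble(report$identify),
                                   -"sequence"),
                     file.path(outdir, "candidates.tsv"))
  }
  if (!is.null(report$qpcr)) {
    readr::write_tsv(report$qpcr, file.path(outdir, "regulation_calls.tsv"))
  }
  invisible(outdir)
}

#' @export
print.famscan_report <- function(x, ...) {
  cat("<famscan pipeline report>\n")
  print(x$headline)
  invisible(x)
}
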