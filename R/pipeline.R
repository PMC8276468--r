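#' Run the full analysis pipeline on a synthetic or file-based bundle
#'
#' Executes the stages in order — abundance aggregation, MAG quality
#' filtering, trait classification, virus-host association (similarity +
#' CRISPR + composition), and AMG flagging — writing every stage's output
#' under `out_dir` together with a JSON reproducibility manifest (config
#' hash, package version, per-stage row counts). Identical config and inputs
#' give byte-identical outputs.
#'
#' @param config A list (or path to a YAML file) with fields:
#'   * `seed` — integer seed (required).
#'   * `out_dir` — output directory (required).
#'   * `synthetic` — optional list of [synthetic_config()] arguments; when
#'     present the input bundle is generated.
#'   * `inputs` — otherwise, named paths: `hosts_fasta`, `viruses_fasta`,
#'     `assignments_tsv`, `qc_tsv`, `annotations_tsv`,
#'     `viral_annotations_tsv`, and optional `blast_tsv`.
#'   * `thresholds` — optional overrides: `min_completeness` (50),
#'     `max_contamination` (10), `min_bitscore` (50), `max_evalue` (0.001),
#'     `d_max` (0.0015), `min_virus_len` (5000), `max_mismatch` (2).
#'   * `abundance_rank` — rank for the abundance table (default "phylum").
#' @return A list of class `pipeline_result` with the per-stage tibbles and
#'   the manifest; outputs are also written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  known <- c("seed", "out_dir", "synthetic", "inputs", "thresholds",
             "abundance_rank", "pathway_catalog", "ns_ko_catalog")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$seed) || is.null(config$out_dir)) {
    abort("config must set `seed` and `out_dir`")
  }
  th <- config$thresholds %||% list()
  defaults <- list(min_completeness = 50, max_contamination = 10,
                   min_bitscore = 50, max_evalue = 0.001, d_max = 0.0015,
                   min_virus_len = 5000, max_mismatch = 2)
  bad_th <- setdiff(names(th), names(defaults))
  if (length(bad_th)) {
    abort(sprintf("unknown threshold key(s): %s", paste(bad_th, collapse = ", ")))
  }
  th <- utils::modifyList(defaults, th)
  rank <- config$abundance_rank %||% "phylum"
  catalog <- if (!is.null(config$pathway_catalog)) {
    read_pathway_catalog(config$pathway_catalog)
  } else {
    default_pathway_catalog()
  }
  ns_catalog <- if (!is.null(config$ns_ko_catalog)) {
    read_ns_ko_catalog(config$ns_ko_catalog)
  } else {
    default_ns_ko_catalog()
  }

  bundle <- load_pipeline_inputs(config, catalog)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_rows <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    stage_rows[[name]] <<- if (is.data.frame(res)) nrow(res) else NA_integer_
    res
  }

  abund <- run_stage("abundance",
                     summarize_abundance(bundle$assignments, rank = rank))
  qc <- run_stage("mag_qc", filter_mags(
    bundle$qc, min_completeness = th$min_completeness,
    max_contamination = th$max_contamination
  ))
  tiers <- quality_tiers(filter(qc, .data$kept))
  traits <- run_stage("traits", suppressMessages(
    classify_traits(bundle$annotations, catalog)
  ))
  vh_edges <- run_stage("virus_host", {
    sim <- if (nrow(bundle$similarity) > 0) {
      filter_similarity_links(bundle$similarity, min_bitscore = th$min_bitscore,
                              max_evalue = th$max_evalue)
    } else {
      NULL
    }
    spacers <- detect_spacers(bundle$hosts)
    crispr <- if (nrow(spacers) > 0) {
      match_spacers(spacers, bundle$viruses, max_mismatch = th$max_mismatch)
    } else {
      NULL
    }
    comp <- assign_by_composition(bundle$viruses, bundle$hosts,
                                  d_max = th$d_max,
                                  min_virus_len = th$min_virus_len)
    bind_rows(sim, crispr, comp)
  })
  network <- build_network(vh_edges,
                           virus_taxonomy = bundle$virus_taxonomy,
                           host_taxonomy = bundle$host_taxonomy)
  amgs <- run_stage("amg", flag_amgs(bundle$viral_annotations, ns_catalog))
  cogs <- cog_category_summary(bundle$viral_annotations)

  readr::write_tsv(abund, file.path(out_dir, paste0("abundance_", rank, ".tsv")))
  readr::write_tsv(qc, file.path(out_dir, "mag_qc.tsv"))
  readr::write_tsv(as_tibble(traits), file.path(out_dir, "trait_flags.tsv"))
  readr::write_tsv(attr(traits, "completeness"),
                   file.path(out_dir, "pathway_completeness.tsv"))
  readr::write_tsv(vh_edges, file.path(out_dir, "vh_edges.tsv"))
  readr::write_tsv(network$edges, file.path(out_dir, "network_edges.tsv"))
  readr::write_tsv(amgs, file.path(out_dir, "amg.tsv"))
  readr::write_tsv(cogs, file.path(out_dir, "cog_summary.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("hadalomics")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    thresholds = th,
    stages = names(stage_rows),
    stage_rows = stage_rows,
    tiers = as.list(tiers)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(
    abundance = abund, mag_qc = qc, tiers = tiers, traits = traits,
    vh_edges = vh_edges, network = network, amgs = amgs,
    cog_summary = cogs, manifest = manifest,
    truth = bundle$truth
  ), class = "pipeline_result")
}

load_pipeline_inputs <- function(config, catalog) {
  if (!is.null(config$synthetic)) {
    syn_args <- config$synthetic
    syn_args$seed <- syn_args$seed %||% config$seed
    cfg <- do.call(synthetic_config, syn_args)
    b <- synthesize_metagenome(cfg, pathway_catalog = catalog)
    host_tax <- setNames(
      parse_lineage(b$hosts$lineage)$class, b$hosts$genome_id
    )
    virus_tax <- setNames(rep("synthetic_virus", nrow(b$viruses)),
                          b$viruses$virus_id)
    return(list(
      hosts = b$hosts, viruses = as_seq_tbl(b$viruses),
      assignments = b$assignments, qc = b$qc, annotations = b$annotations,
      viral_annotations = b$viral_annotations, similarity = b$similarity,
      host_taxonomy = host_tax, virus_taxonomy = virus_tax, truth = b$truth
    ))
  }
  paths <- config$inputs
  if (is.null(paths)) abort("config needs either `synthetic` or `inputs`")
  required <- c("hosts_fasta", "viruses_fasta", "assignments_tsv", "qc_tsv",
                "annotations_tsv", "viral_annotations_tsv")
  for (p in required) {
    if (is.null(paths[[p]])) abort(sprintf("config inputs missing `%s`", p))
    if (!file.exists(paths[[p]])) {
      abort(sprintf("input path does not exist: %s", paths[[p]]))
    }
  }
  list(
    hosts = read_seq_fasta(paths$hosts_fasta),
    viruses = read_seq_fasta(paths$viruses_fasta),
    assignments = read_assignments_tsv(paths$assignments_tsv),
    qc = read_qc_tsv(paths$qc_tsv),
    annotations = readr::read_tsv(paths$annotations_tsv,
      col_types = readr::cols(.default = readr::col_character())),
    viral_annotations = read_viral_annotations_tsv(paths$viral_annotations_tsv),
    similarity = if (!is.null(paths$blast_tsv)) read_blast_tab(paths$blast_tsv)
      else empty_blast_tbl(),
    host_taxonomy = NULL, virus_taxonomy = NULL, truth = NULL
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  stages: %s\n", paste(x$manifest$stages, collapse = ", ")))
  cat(sprintf("  MAGs kept: %d of %d | virus-host edges: %d | AMGs: %d\n",
              sum(x$mag_qc$kept), nrow(x$mag_qc), nrow(x$vh_edges),
              nrow(x$amgs)))
  invisible(x)
}
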