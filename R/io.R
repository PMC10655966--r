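#' Write encoded genealogies to an array archive with a manifest
#'
#' Saves a list of encoding tensors (see [encoding_tensor()]) as one
#' compressed R array archive keyed by example id, plus a JSON sidecar
#' manifest recording `n`, the scenario, seed and labels.
#'
#' @param tensors named list of `(n-1) x (n-1) x 3` arrays.
#' @param file output path for the archive (`.rds`).
#' @param manifest list of per-dataset metadata (scenario, seed, labels...).
#' @return `file`, invisibly; the manifest is written next to it as
#'   `<file>.json`.
#' @export
write_encodings <- function(tensors, file, manifest = list()) {
  stopifnot(is.list(tensors), length(tensors) > 0)
  if (is.null(names(tensors)) || any(names(tensors) == "")) {
    names(tensors) <- sprintf("ex%06d", seq_along(tensors))
  }
  saveRDS(tensors, file, compress = "gzip")
  manifest$ids <- names(tensors)
  manifest$n <- dim(tensors[[1L]])[1L] + 1L
  jsonlite::write_json(manifest, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}

#' Read encoded genealogies written by [write_encodings()]
#' @param file archive path.
#' @return A list: `tensors`, `manifest`.
#' @export
read_encodings <- function(file) {
  list(tensors = readRDS(file),
       manifest = jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE))
}

#' Read a genealogy from a newick file or string
#'
#' Branch lengths are interpreted as generations; the tree must be rooted,
#' binary and ultrametric.
#'
#' @param source a file path or a newick string.
#' @param derived_leaves optional tip labels (or indices) carrying the
#'   derived allele at the focal site.
#' @return A [genealogy()].
#' @export
read_genealogy_newick <- function(source, derived_leaves = NULL) {
  phy <- if (file.exists(source)) ape::read.tree(source) else
    ape::read.tree(text = source)
  if (is.null(phy)) stop("could not parse newick input")
  genealogy_from_phylo(phy, derived_leaves = derived_leaves)
}

#' Ingest a marginal genealogy from a tskit tree-sequence file
#'
#' Adapter for externally produced tree sequences (coalescent or forward
#' simulators, ARG-inference tools): extracts the marginal tree at a focal
#' position — and the derived-carrier set of the biallelic variant nearest
#' that position, if any — by shelling out to the Python `tskit` library,
#' then rebuilds the genealogy in R. Requires a `python` interpreter with
#' `tskit` importable on the PATH.
#'
#' @param path a `.trees` file.
#' @param focal_position position in bp.
#' @param python interpreter to use.
#' @return A [genealogy()].
#' @export
ingest_tree_sequence <- function(path, focal_position, python = "python") {
  if (!file.exists(path)) stop("tree-sequence file not found: ", path)
  script <- system.file("python", "ts_focal_tree.py", package = "popdann",
                        mustWork = TRUE)
  out <- suppressWarnings(
    system2(python, c(script, shQuote(path), format(focal_position, scientific = FALSE)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("tskit ingest failed: ", paste(out, collapse = "\n"))
  }
  parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  phy <- ape::read.tree(text = parsed$newick)
  derived <- if (length(parsed$derived)) as.character(parsed$derived) else NULL
  genealogy_from_phylo(phy, derived_leaves = derived)
}

#' Export a simulated region as ms-style text
#'
#' @param region a `region_sim` with genotypes.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_ms <- function(region, file) {
  stopifnot(inherits(region, "region_sim"), !is.null(region$genotypes))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ms %d 1", region$n), "", "//",
               sprintf("segsites: %d", region$n_sites),
               paste("positions:",
                     paste(formatC(region$positions / region$L, digits = 6,
                                   format = "f"), collapse = " "))), con)
  G <- t(region$genotypes)  # haplotype rows
  writeLines(apply(G, 1L, paste, collapse = ""), con)
  invisible(file)
}

#' Export a simulated region as a minimal VCF
#'
#' Haploid GT columns, one sample per sequence, positions rounded to
#' integer bp (1-based in the VCF, as the format requires).
#'
#' @param region a `region_sim` with genotypes.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_region_vcf <- function(region, file) {
  stopifnot(inherits(region, "region_sim"), !is.null(region$genotypes))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=1,length=%d>", as.integer(region$L)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sprintf("hap%d", seq_len(region$n))),
                     collapse = "\t")), con)
  if (region$n_sites > 0L) {
    pos <- pmax(1L, as.integer(round(region$positions)))
    rows <- vapply(seq_len(region$n_sites), function(i) {
      paste(c("1", pos[i], ".", "A", "T", ".", "PASS", ".", "GT",
              region$genotypes[i, ]), collapse = "\t")
    }, character(1))
    writeLines(rows, con)
  }
  invisible(file)
}

#' Read a scenario configuration from a YAML file
#'
#' The file names a preset and its arguments, e.g.
#' ```yaml
#' preset: relernn_demography
#' n_samples: 32
#' L: 300000
#' ```
#'
#' @param file YAML path.
#' @return A `scenario_pair`.
#' @export
read_scenario_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$preset)) stop("scenario config needs a 'preset' field")
  presets <- list(
    tree_inference_only = scenario_tree_inference_only,
    bottleneck_8000 = function(...) scenario_bottleneck(8000, ...),
    bottleneck_5000 = function(...) scenario_bottleneck(5000, ...),
    bottleneck_2000 = function(...) scenario_bottleneck(2000, ...),
    bottleneck_500 = function(...) scenario_bottleneck(500, ...),
    extreme = scenario_extreme,
    relernn_bgs = scenario_relernn_bgs,
    relernn_demography = scenario_relernn_demography,
    no_misspec = scenario_no_misspec)
  fn <- presets[[cfg$preset]]
  if (is.null(fn)) stop("configuration error: unknown preset ", cfg$preset)
  do.call(fn, cfg[setdiff(names(cfg), "preset")])
}
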