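# File formats: model-spec documents (JSON or YAML), sample-table CSV with
# a fixed column order, and run manifests.

model_to_document <- function(model) {
  list(
    metabolites = as.list(model$metabolites),
    reactions = lapply(unname(model$reactions), function(r)
      list(id = r$id, name = r$name,
           stoichiometry = as.list(r$stoichiometry),
           atp_produced = r$atp_produced, reversible = r$reversible,
           enzyme = if (is.na(r$enzyme)) NULL else r$enzyme,
           pathway = r$pathway)),
    enzymes = lapply(unname(model$enzymes), function(e)
      list(id = e$id, genes = as.list(e$genes), mw = e$mw,
           n_subunits = e$n_subunits, k_eff = e$k_eff,
           dG_ref = e$dG_ref, category = e$category)),
    atp_registry = as.list(model$atp_registry),
    parameters = model$params)
}

document_to_model <- function(doc) {
  for (field in c("reactions", "enzymes", "atp_registry", "parameters"))
    if (is.null(doc[[field]]))
      stop("model spec: missing top-level key '", field, "'")
  reactions <- lapply(doc$reactions, function(r) {
    enz <- r$enzyme
    if (is.null(enz) || !length(enz)) enz <- NA_character_
    reaction_spec(r$id, r$name,
                  unlist(r$stoichiometry),
                  atp_produced = r$atp_produced %||% 0,
                  reversible = isTRUE(r$reversible),
                  enzyme = as.character(enz),
                  pathway = r$pathway %||% "exchange")
  })
  enzymes <- lapply(doc$enzymes, function(e)
    enzyme_spec(e$id, unlist(e$genes), e$mw, e$n_subunits, e$k_eff,
                e$dG_ref, e$category %||% "soluble"))
  params <- lapply(doc$parameters, as.numeric)
  registry <- as.character(unlist(doc$atp_registry))
  if (length(registry) != 8)
    stop("model spec: atp_registry must have exactly 8 entries, got ",
         length(registry))
  model_spec(reactions, enzymes, params, atp_registry = registry)
}

#' Write a model spec file
#'
#' Serialises a model to a structured text document with top-level keys
#' `metabolites`, `reactions`, `enzymes`, `atp_registry`, `parameters`.
#' The format follows the file extension: `.json` or `.yaml`/`.yml`.
#' Read/write round trips are lossless.
#'
#' @param model an `aero_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "aero_model"))
  doc <- model_to_document(model)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    writeLines(yaml::as.yaml(doc, precision = 15), path)
  } else {
    stop("unsupported model-spec extension '", ext,
         "': use .json, .yaml or .yml")
  }
  invisible(path)
}

#' Load a model spec file
#'
#' Parses a JSON or YAML model document and validates every model
#' invariant (see [validate_model()]).
#'
#' @param path path to a `.json`, `.yaml` or `.yml` model spec.
#' @return a validated `aero_model`.
#' @export
load_model_spec <- function(path) {
  if (!file.exists(path)) stop("model spec not found: ", path)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") {
    jsonlite::read_json(path)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported model-spec extension '", ext, "'")
  }
  document_to_model(doc)
}

#' Path to the shipped calibrated model
#'
#' @return path of the default model spec installed with the package.
#' @export
default_model_path <- function() {
  system.file("extdata", "ecoli_coarse_model.json", package = "aerotype",
              mustWork = TRUE)
}

# Fixed, documented column order of the sample-table CSV.
SAMPLE_TABLE_COLUMNS <- c("strain_id", "T", "feasible", "mu", "q_glc",
                          "q_ac", "q_o2", "Y", "f_ATPS", "f_PGK", "f_PYK",
                          "f_ACKr", "f_PPKr", "f_PPK2r", "f_SUCOAS",
                          "f_PRPPS", "n_genes_expressed", "avg_subunits",
                          "aerotype")

#' Write a sample table as CSV
#'
#' Columns are written in the fixed documented order (`strain_id, T,
#' feasible, mu, q_glc, q_ac, q_o2, Y, f_ATPS, f_PGK, f_PYK, f_ACKr,
#' f_PPKr, f_PPK2r, f_SUCOAS, f_PRPPS, n_genes_expressed, avg_subunits,
#' aerotype`), followed by any flux (`v_*`) and driver-specific columns.
#' Plain UTF-8, '.' decimal separator, header row mandatory.
#'
#' @param table an `aero_sample_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path) {
  extra <- setdiff(names(table), SAMPLE_TABLE_COLUMNS)
  ord <- c(intersect(SAMPLE_TABLE_COLUMNS, names(table)), extra)
  utils::write.csv(table[, ord, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a sample table CSV
#'
#' @param path CSV written by [write_sample_table()].
#' @return an `aero_sample_table`.
#' @export
read_sample_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$aerotype <- as.character(out$aerotype)
  class(out) <- c("aero_sample_table", "data.frame")
  out
}

#' Write a run manifest
#'
#' Every pipeline output directory carries exactly one manifest recording
#' the command, the configuration snapshot, the master seed, the package
#' version, MD5 digests of the input and output files, and the start/end
#' timestamps — enough to reproduce every stochastic output.
#'
#' @param dir output directory.
#' @param command subcommand name.
#' @param config configuration snapshot (list).
#' @param seed master seed.
#' @param inputs,outputs file paths to digest.
#' @param started POSIXct start time.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(dir, command, config, seed, inputs = character(),
                           outputs = character(), started = Sys.time()) {
  digest <- function(paths) {
    paths <- paths[file.exists(paths)]
    as.list(tools::md5sum(paths))
  }
  manifest <- list(command = command, config = config, master_seed = seed,
                   tool_version = as.character(utils::packageVersion(
                     "aerotype")),
                   input_digests = digest(inputs),
                   output_digests = digest(outputs),
                   started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
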