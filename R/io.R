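## Flat-file interfaces: FASTA via Biostrings, tables as TSV, set/summary
## outputs as JSON, configuration as YAML.

#' Write / read a reference transcriptome as FASTA
#'
#' @param reference a `reference_set`.
#' @param path output/input FASTA path.
#' @return `write_reference_fasta` returns `path` invisibly;
#'   `read_reference_fasta` returns a `reference_set`.
#' @export
write_reference_fasta <- function(reference, path) {
  s <- Biostrings::DNAStringSet(reference$sequence)
  names(s) <- reference$gene_id
  Biostrings::writeXStringSet(s, filepath = path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  structure(data.frame(gene_id = names(s), sequence = as.character(s),
                       stringsAsFactors = FALSE),
            class = c("reference_set", "data.frame"))
}

#' Write / read a tag library as 2-column TSV
#'
#' Columns `tag_sequence`, `count`. Reading yields a raw library unless
#' `clean = TRUE` is asserted by the caller.
#'
#' @param lib a `tag_library`.
#' @param path TSV path.
#' @param species species label on read.
#' @param clean whether the file holds an already-filtered library.
#' @return the path (write, invisibly) or a `tag_library` (read).
#' @export
write_tag_library <- function(lib, path) {
  utils::write.table(
    data.frame(tag_sequence = names(lib$counts), count = lib$counts),
    file = path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_tag_library
#' @export
read_tag_library <- function(path, species = NA_character_, clean = FALSE) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  tag_library(structure(as.integer(d$count), names = d$tag_sequence),
              species = species, clean = clean)
}

#' Read tag occurrences from FASTA (one record per occurrence)
#'
#' @param path FASTA path.
#' @param species species label.
#' @return a raw `tag_library` aggregated from the records.
#' @export
read_tags_fasta <- function(path, species = NA_character_) {
  s <- Biostrings::readDNAStringSet(path)
  tag_library(count_sequences(as.character(s)), species = species)
}

#' Write simulation truth as TSV
#'
#' Long format: `gene_id`, `species`, `abundance`, `additivity_class`,
#' `dominance_parent` (classes only for amphidiploids).
#'
#' @param truth a `simulation_truth`.
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  sp <- colnames(truth$abundance)
  long <- do.call(rbind, lapply(sp, function(s) {
    d <- data.frame(gene_id = truth$gene_id, species = s,
                    abundance = truth$abundance[, s],
                    additivity_class = NA_character_,
                    dominance_parent = NA_character_,
                    stringsAsFactors = FALSE)
    cl <- truth$classes[truth$classes$amphidiploid == s, , drop = FALSE]
    if (nrow(cl)) {
      i <- match(d$gene_id, cl$gene_id)
      d$additivity_class <- cl$additivity_class[i]
      d$dominance_parent <- cl$dominance_parent[i]
    }
    d
  }))
  utils::write.table(long, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path YAML path.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' Write an expression profile / a generic table as TSV
#'
#' @param x data.frame.
#' @param path TSV path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a tag catalog as TSV (`tag`, `gene_id`, `strand`, `offset`)
#'
#' @param catalog a `tag_catalog`.
#' @param path TSV path.
#' @export
write_catalog <- function(catalog, path) {
  write_tsv(catalog$entries, path)
}

#' Write Venn region counts (or any simple list) as JSON
#'
#' @param x list or named vector.
#' @param path JSON path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(as.list(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
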