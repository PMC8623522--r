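# Interchange formats: FASTA, topology, label and accessibility TSVs,
# corpus directories, prediction tables and evaluation reports.

#' Read / write protein sequences (FASTA)
#'
#' Thin wrappers around Biostrings returning plain named character
#' vectors.
#'
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Write a synthetic (or user) corpus to an interchange directory
#'
#' Produces `sequences.fasta`, `topology.tsv` (`id`, per-residue label
#' string), `labels.tsv` (`protein_id`, `position`, `residue`, `label`)
#' and `accessibility.tsv` (`protein_id`, `position`, `residue`, `rsa`).
#'
#' @param proteins List of [annotated_protein()] objects.
#' @param dir Output directory (created if missing).
#' @export
write_corpus <- function(proteins, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(proteins, `[[`, "", "id")
  write_fasta(stats::setNames(vapply(proteins, `[[`, "", "sequence"),
                              ids),
              file.path(dir, "sequences.fasta"))
  topo <- data.frame(
    id = ids,
    topology = vapply(proteins, function(p)
      paste(unclass(p$topology), collapse = ""), character(1)))
  utils::write.table(topo, file.path(dir, "topology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lab <- do.call(rbind, lapply(proteins, function(p) {
    if (is.null(p$labels)) return(NULL)
    data.frame(protein_id = p$id,
               position = seq_len(nchar(p$sequence)),
               residue = strsplit(p$sequence, "")[[1]],
               label = p$labels)
  }))
  if (!is.null(lab))
    utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  rsa <- do.call(rbind, lapply(proteins, function(p) {
    if (is.null(p$rsa)) return(NULL)
    data.frame(protein_id = p$id,
               position = seq_len(nchar(p$sequence)),
               residue = strsplit(p$sequence, "")[[1]],
               rsa = round(p$rsa, 4))
  }))
  if (!is.null(rsa))
    utils::write.table(rsa, file.path(dir, "accessibility.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a corpus directory back into annotated proteins
#'
#' @param dir Directory written by [write_corpus()].
#' @return List of [annotated_protein()] objects.
#' @export
read_corpus <- function(dir) {
  seqs <- read_fasta(file.path(dir, "sequences.fasta"))
  topo <- utils::read.table(file.path(dir, "topology.tsv"), sep = "\t",
                            header = TRUE, colClasses = "character")
  lab_path <- file.path(dir, "labels.tsv")
  labs <- if (file.exists(lab_path))
    utils::read.table(lab_path, sep = "\t", header = TRUE,
                      colClasses = c("character", "integer",
                                     "character", "character"))
  else NULL
  rsa_path <- file.path(dir, "accessibility.tsv")
  rsas <- if (file.exists(rsa_path))
    utils::read.table(rsa_path, sep = "\t", header = TRUE)
  else NULL
  lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    trow <- topo$topology[topo$id == id]
    if (length(trow) != 1)
      stop("missing or duplicated topology for ", id)
    labels <- NULL
    if (!is.null(labs) && any(labs$protein_id == id)) {
      sub <- labs[labs$protein_id == id, ]
      labels <- sub$label[order(sub$position)]
    }
    rsa <- NULL
    if (!is.null(rsas) && any(rsas$protein_id == id)) {
      sub <- rsas[rsas$protein_id == id, ]
      rsa <- sub$rsa[order(sub$position)]
    }
    annotated_protein(id, s, parse_topology(trow, length = nchar(s)),
                      labels = labels, rsa = rsa)
  })
}

#' Write / read per-residue prediction tables
#'
#' TSV round-trip of [predict_disorder()] output.
#'
#' @param pred Prediction data frame.
#' @param path File path.
#' @export
write_predictions <- function(pred, path) {
  num <- vapply(pred, is.numeric, logical(1)) &
    !names(pred) %in% c("position")
  pred[num] <- lapply(pred[num], round, digits = 5)
  utils::write.table(pred, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read a topology file (id to per-residue string)
#' @param path TSV with columns `id`, `topology`.
#' @export
read_topology_file <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  stats::setNames(df$topology, df$id)
}
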