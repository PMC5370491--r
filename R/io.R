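# File parsing and writing. Conventions: TSV with header rows, 1-based
# positions, aligned FASTA panels with `>id|species|component` headers
# (plain headers accepted, the header then doubles as the species
# label).

#' Read an aligned barcode reference panel from FASTA
#'
#' @param path FASTA file of equal-length aligned sequences. Headers of
#'   the form `id|species|component` are parsed into the panel fields;
#'   plain headers are used as both id and species with component
#'   `target`.
#' @return a [barcode_panel()].
#' @export
read_reference_alignment <- function(path) {
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) stop("no sequences in FASTA file: ", path)
  seqs <- unname(toupper(vapply(as.character(dna), paste, "",
                                collapse = "")))
  parts <- strsplit(names(dna), "|", fixed = TRUE)
  id <- vapply(parts, `[`, "", 1)
  species <- vapply(parts, function(p) if (length(p) >= 2) p[2] else p[1],
                    "")
  component <- vapply(parts, function(p)
    if (length(p) >= 3) p[3] else "target", "")
  barcode_panel(seqs, id = id, species = species, component = component)
}

#' Write a barcode panel to FASTA
#'
#' @param panel a [barcode_panel()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_reference_alignment <- function(panel, path) {
  hdr <- paste(panel$id, panel$species, panel$component, sep = "|")
  writeLines(paste0(">", hdr, "\n", panel$sequences), path)
  invisible(path)
}

#' Read sample reads from FASTQ, FASTA or plain text
#'
#' FASTQ files (first character `@`) and FASTA files (first character
#' `>`) are parsed with ape; any other file is treated as plain
#' one-read-per-line text.
#'
#' @param path input file.
#' @return character vector of read sequences (upper case).
#' @export
read_sample_reads <- function(path) {
  first <- substr(readLines(path, n = 1), 1, 1)
  if (length(first) == 0) return(character())
  seqs <- if (first == "@") ape::read.fastq(path)
          else if (first == ">") ape::read.FASTA(path)
          else NULL
  if (is.null(seqs))
    return(toupper(trimws(readLines(path))))
  unname(toupper(vapply(as.character(seqs), paste, "", collapse = "")))
}

#' Read a quartet table TSV
#'
#' Expected columns: `species`, `individual`, `contig`, `position`
#' (1-based), `nA`, `nC`, `nG`, `nT`, with a header row. Malformed rows
#' (negative or missing counts) and duplicated
#' (species, individual, contig, position) rows raise errors naming the
#' offending line.
#'
#' @param path input TSV.
#' @return quartet data frame (column `position` renamed to `pos`);
#'   empty files yield an empty table with a warning.
#' @export
read_quartet_table <- function(path) {
  empty <- data.frame(species = character(), individual = character(),
                      contig = character(), pos = integer(),
                      nA = integer(), nC = integer(), nG = integer(),
                      nT = integer(), stringsAsFactors = FALSE)
  if (file.size(path) == 0 || length(readLines(path, n = 1)) == 0) {
    warning("empty quartet table: ", path)
    return(empty)
  }
  q <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "individual", "contig", "position",
            "nA", "nC", "nG", "nT")
  miss <- setdiff(need, names(q))
  if (length(miss))
    stop("quartet table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(q) == 0) {
    warning("empty quartet table: ", path)
    return(empty)
  }
  cnt <- as.matrix(q[, c("nA", "nC", "nG", "nT")])
  bad <- which(rowSums(is.na(cnt) | cnt < 0) > 0)
  if (length(bad))
    stop("malformed quartet counts at line ", bad[1] + 1L, " of ", path)
  key <- paste(q$species, q$individual, q$contig, q$position)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (species, individual, contig, position) row at line ",
         dup[1] + 1L, " of ", path)
  names(q)[names(q) == "position"] <- "pos"
  q[, c("species", "individual", "contig", "pos", need[5:8])]
}

#' Write a quartet table TSV
#'
#' @param quartets quartet data frame (internal `pos` column written as
#'   `position`, 1-based).
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_quartet_table <- function(quartets, path) {
  q <- .check_quartets(quartets)
  out <- data.frame(species = q$species, individual = q$individual,
                    contig = q$contig, position = q$pos,
                    nA = q$nA, nC = q$nC, nG = q$nG, nT = q$nT)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata TSV
#'
#' Columns: `species`, `individual`, `technician`, `entry_date`,
#' `shipment_date`, `center`, and optionally `flowcell`, `lane`. Dates
#' are parsed as ISO `Date`s; entry dates must not follow shipment
#' dates.
#'
#' @param path input TSV.
#' @return metadata data frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "individual", "technician", "entry_date",
            "shipment_date", "center")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  md$entry_date <- as.Date(md$entry_date)
  md$shipment_date <- as.Date(md$shipment_date)
  if (any(md$entry_date > md$shipment_date, na.rm = TRUE))
    stop("entry dates must precede shipment dates")
  md
}

#' Write a sample metadata TSV
#' @param metadata metadata data frame.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write genotype calls as a VCF-like TSV
#'
#' One row per (contig, position): the major allele as reference, the
#' alternative called alleles, and per-individual genotype and
#' posterior columns.
#'
#' @param gt result of [call_genotypes()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_genotype_table <- function(gt, path) {
  calls <- gt$calls
  inds <- sort(unique(calls$individual))
  key <- paste(calls$species, calls$contig, calls$pos, sep = "\r")
  idx <- split(seq_len(nrow(calls)), key)
  rows <- lapply(idx, function(ii) {
    r <- calls[ii, , drop = FALSE]
    cal <- r[r$called, , drop = FALSE]
    a <- unlist(strsplit(paste0(cal$allele1, cal$allele2), ""))
    ref <- if (length(a)) names(sort(table(a), decreasing = TRUE))[1]
           else NA_character_
    alt <- setdiff(sort(unique(a)), ref)
    g <- setNames(rep("./.", length(inds)), inds)
    p <- setNames(rep(NA_real_, length(inds)), inds)
    g[r$individual[r$called]] <-
      paste(cal$allele1, cal$allele2, sep = "/")
    p[r$individual] <- r$posterior
    out <- data.frame(species = r$species[1], contig = r$contig[1],
                      position = r$pos[1], ref = ref,
                      alt = if (length(alt)) paste(alt, collapse = ",")
                            else ".",
                      stringsAsFactors = FALSE)
    for (ind in inds) {
      out[[paste0(ind, "_gt")]] <- g[[ind]]
      out[[paste0(ind, "_pp")]] <- round(p[[ind]], 4)
    }
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$species, tab$contig, tab$position), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records inputs, thresholds, seed and package version so that
#' deterministic runs can be reproduced bit for bit.
#'
#' @param path output JSON file.
#' @param inputs named list of input paths.
#' @param params named list of thresholds/settings.
#' @param seed the seed used (or NA).
#' @return invisibly, the path.
#' @export
write_manifest <- function(path, inputs = list(), params = list(),
                           seed = NA) {
  jsonlite::write_json(
    list(package = "seqcontam",
         version = as.character(utils::packageVersion("seqcontam")),
         timestamp = format(Sys.time(), tz = "UTC"),
         inputs = inputs, params = params, seed = seed),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
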