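# Aligned sequence sets: the universal input of the pipeline.

PURE_BASES <- c("A", "C", "G", "T")
AMBIGUITY_CODES <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
GAP_CHAR <- "-"
ALLOWED_CHARS <- c(PURE_BASES, AMBIGUITY_CODES, GAP_CHAR)

#' Construct an aligned sequence set
#'
#' An `alignment_set` holds equal-length aligned nucleotide sequences together
#' with a species (and optional population) label per sequence. It is the
#' input type of every analysis stage: distance computation, divergence
#' summaries, identification, tree building, diagnostic-site detection and
#' haplotype collapsing.
#'
#' Residues are uppercased on construction and restricted to the IUPAC
#' nucleotide alphabet (`A C G T`, the ambiguity codes `R Y S W K M B D H V N`)
#' plus the gap character `-`.
#'
#' @param sequences Named character vector of aligned sequences (names are the
#'   sequence ids), or a character matrix with one row per sequence and
#'   rownames as ids.
#' @param species Character vector of species labels, one per sequence.
#' @param population Optional character vector of population labels; empty
#'   strings are allowed.
#' @return An object of class `alignment_set` with components `mat` (character
#'   matrix, one row per sequence), `meta` (data.frame with columns `id`,
#'   `species`, `population`).
#' @examples
#' aln <- alignment_set(c(a1 = "ACGT", a2 = "ACGA"),
#'                      species = c("X", "X"))
#' alignment_length(aln)
#' @export
alignment_set <- function(sequences, species, population = NULL) {
  if (is.matrix(sequences)) {
    mat <- sequences
    ids <- rownames(mat)
  } else {
    ids <- names(sequences)
    if (is.null(ids)) stop("sequences must be named by sequence id")
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1) {
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    }
    mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
    rownames(mat) <- ids
  }
  if (any(duplicated(ids))) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mat[] <- toupper(mat)
  bad <- setdiff(unique(as.vector(mat)), ALLOWED_CHARS)
  if (length(bad) > 0) {
    stop("alphabet error: illegal character(s) ", paste(bad, collapse = " "),
         " (allowed: IUPAC nucleotide codes and '-')")
  }
  species <- as.character(species)
  if (length(species) != nrow(mat)) {
    stop("species must have one label per sequence")
  }
  if (any(is.na(species) | species == "")) {
    stop("mapping error: every sequence needs a non-empty species label")
  }
  if (is.null(population)) population <- rep("", nrow(mat))
  meta <- data.frame(id = ids, species = species,
                     population = as.character(population),
                     stringsAsFactors = FALSE)
  structure(list(mat = mat, meta = meta), class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("Aligned sequence set:", nrow(x$mat), "sequences x",
      ncol(x$mat), "columns;",
      length(unique(x$meta$species)), "species\n")
  invisible(x)
}

#' Number of alignment columns
#' @param aln An `alignment_set`.
#' @return Integer number of columns.
#' @export
alignment_length <- function(aln) ncol(aln$mat)

#' Sequences as character strings
#' @param aln An `alignment_set`.
#' @return Named character vector of sequence strings.
#' @export
alignment_strings <- function(aln) {
  out <- apply(aln$mat, 1, paste, collapse = "")
  names(out) <- aln$meta$id
  out
}

#' Species map of an alignment
#' @param aln An `alignment_set`.
#' @return Named character vector: species label per sequence id.
#' @export
species_map <- function(aln) {
  stats::setNames(aln$meta$species, aln$meta$id)
}

#' Read an aligned FASTA plus a sample map
#'
#' The sample map is a tab-separated file with header
#' `id<TAB>species<TAB>population` (population may be empty or the column
#' absent). Every FASTA id must appear in the map; records keep file order.
#'
#' @param fasta_path Path to an aligned multi-FASTA file.
#' @param samplemap_path Path to the tab-separated sample map.
#' @return An `alignment_set`.
#' @export
read_alignment <- function(fasta_path, samplemap_path) {
  seqs <- read_fasta(fasta_path)
  map <- read_sample_map(samplemap_path)
  missing <- setdiff(names(seqs), map$id)
  if (length(missing) > 0) {
    stop("mapping error: FASTA id(s) absent from sample map: ",
         paste(missing, collapse = ", "))
  }
  map <- map[match(names(seqs), map$id), ]
  alignment_set(seqs, species = map$species, population = map$population)
}

# Minimal aligned-FASTA reader. Deliberately strict: unlike generic readers it
# must reject ragged alignments and foreign characters with specific errors.
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path)
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)  # id = first token of the header
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(gsub("\\s", "", x), collapse = ""), "")
  if (length(seqs) != length(ids)) stop("FASTA record without sequence in ", path)
  names(seqs) <- ids
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    stop("alignment error: sequences in ", path, " have unequal lengths (",
         paste(sort(unique(lens)), collapse = ", "), ")")
  }
  seqs
}

read_sample_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  map <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "")
  if (!all(c("id", "species") %in% names(map))) {
    stop("sample map must have header columns 'id' and 'species': ", path)
  }
  if (!"population" %in% names(map)) map$population <- ""
  map$population[is.na(map$population)] <- ""
  map[, c("id", "species", "population")]
}

#' Write an alignment and its sample map
#'
#' Inverse of [read_alignment()]: writing then reading reproduces residues and
#' labels exactly.
#'
#' @param aln An `alignment_set`.
#' @param fasta_path Output FASTA path.
#' @param samplemap_path Output sample-map path (tab-separated).
#' @return Invisibly, `aln`.
#' @export
write_alignment <- function(aln, fasta_path, samplemap_path) {
  seqs <- alignment_strings(aln)
  writeLines(paste0(">", names(seqs), "\n", seqs), fasta_path)
  utils::write.table(aln$meta, samplemap_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(aln)
}

#' Extract a column range from an alignment
#'
#' Used to delimit a sub-region (for example ITS2 within a full ITS
#' alignment) from annotation coordinates. Coordinates are 1-based and
#' inclusive, the convention used in all user-facing files and reports.
#'
#' @param aln An `alignment_set`.
#' @param start First column (1-based, inclusive).
#' @param end Last column (1-based, inclusive).
#' @return An `alignment_set` covering columns `start..end`; labels preserved.
#' @export
extract_region <- function(aln, start, end) {
  n <- alignment_length(aln)
  if (!is.numeric(start) || !is.numeric(end) ||
      start < 1 || end > n || start > end) {
    stop("range error: region [", start, ", ", end,
         "] invalid for alignment of length ", n)
  }
  mat <- aln$mat[, start:end, drop = FALSE]
  alignment_set(mat, species = aln$meta$species,
                population = aln$meta$population)
}

#' Collapse aligned sequences into haplotypes
#'
#' Groups sequences that are identical under the chosen policy. Under
#' `"strict"` equality is exact string equality after uppercasing, with gaps
#' significant and ambiguity codes matching only themselves.
#' `"ignore_gap_only_columns"` first drops columns that are gaps in every
#' sequence of the grouping scope, then compares strictly.
#'
#' @param aln An `alignment_set`.
#' @param scope `"global"` (one pool) or `"per_species"` (collapse within each
#'   species separately).
#' @param gap_policy `"strict"` or `"ignore_gap_only_columns"`.
#' @return A `haplotype_table`: data.frame with columns `haplotype_id`,
#'   `species` (empty under global scope), `n_members`, `member_ids`
#'   (comma-separated), `sequence` (representative residues). Haplotypes are
#'   ordered by decreasing member count, ties broken by first-seen member.
#' @examples
#' aln <- alignment_set(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGA"),
#'                      species = c("X", "X", "Y"))
#' collapse_haplotypes(aln)
#' @export
collapse_haplotypes <- function(aln,
                                scope = c("global", "per_species"),
                                gap_policy = c("strict",
                                               "ignore_gap_only_columns")) {
  scope <- match.arg(scope)
  gap_policy <- match.arg(gap_policy)
  if (nrow(aln$mat) == 0) stop("empty alignment")
  groups <- if (scope == "global") {
    list(global = seq_len(nrow(aln$mat)))
  } else {
    split(seq_len(nrow(aln$mat)), factor(aln$meta$species,
                                         levels = unique(aln$meta$species)))
  }
  out <- list()
  for (g in names(groups)) {
    rows <- groups[[g]]
    mat <- aln$mat[rows, , drop = FALSE]
    if (gap_policy == "ignore_gap_only_columns" && ncol(mat) > 0) {
      keep <- colSums(mat != GAP_CHAR) > 0
      key_mat <- mat[, keep, drop = FALSE]
    } else {
      key_mat <- mat
    }
    keys <- apply(key_mat, 1, paste, collapse = "")
    first_seen <- !duplicated(keys)
    uniq <- keys[first_seen]
    counts <- as.vector(table(factor(keys, levels = uniq)))
    ord <- order(-counts, match(uniq, keys))
    uniq <- uniq[ord]
    counts <- counts[ord]
    ids <- aln$meta$id[rows]
    prefix <- if (scope == "global") "Hap" else paste0(g, "_Hap")
    for (k in seq_along(uniq)) {
      members <- ids[keys == uniq[k]]
      rep_row <- rows[keys == uniq[k]][1]
      out[[length(out) + 1]] <- data.frame(
        haplotype_id = paste0(prefix, "_", k),
        species = if (scope == "global") "" else g,
        n_members = counts[k],
        member_ids = paste(members, collapse = ","),
        sequence = paste(aln$mat[rep_row, ], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  attr(tab, "scope") <- scope
  attr(tab, "gap_policy") <- gap_policy
  class(tab) <- c("haplotype_table", "data.frame")
  tab
}

#' Reduce an alignment to one representative per haplotype
#'
#' @param aln An `alignment_set`.
#' @param ... Passed to [collapse_haplotypes()].
#' @return An `alignment_set` containing the first-seen member of each
#'   haplotype.
#' @export
haplotype_representatives <- function(aln, ...) {
  ht <- collapse_haplotypes(aln, ...)
  reps <- vapply(strsplit(ht$member_ids, ",", fixed = TRUE), `[`, "", 1)
  keep <- match(reps, aln$meta$id)
  alignment_set(aln$mat[keep, , drop = FALSE],
                species = aln$meta$species[keep],
                population = aln$meta$population[keep])
}

#' Write a haplotype table as TSV
#' @param ht A `haplotype_table`.
#' @param path Output path.
#' @return Invisibly, `ht`.
#' @export
write_haplotype_table <- function(ht, path) {
  utils::write.table(as.data.frame(ht), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ht)
}
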