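# Readers/writers for the on-disk formats: STRING-style weighted edge lists,
# GAF-like annotation tables, FASTA sequences, two-column ID maps and the
# domain tables (protein->domain, domain-domain interactions, domain->GO).
# All tabular formats are TSV; lines starting with '#' are comments.

read_tsv_table <- function(path, n_min_cols, what) {
  if (!file.exists(path)) stopf("%s: file not found: %s", what, path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stopf("%s: empty file: %s", what, path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < n_min_cols)) {
    bad <- lineno[which(ncols < n_min_cols)[1]]
    stopf("%s: line %d has fewer than %d tab-separated columns", what, bad,
          n_min_cols)
  }
  list(fields = fields, lineno = lineno)
}

#' Read a weighted protein-protein interaction edge list
#'
#' Parses a STRING-style TSV (`proteinA proteinB score`) into an undirected
#' weighted [igraph::igraph] graph. Duplicate `A-B`/`B-A` rows are collapsed
#' keeping the maximum weight, self-loops are dropped (their count is
#' reported with a message), and scores are stored exactly as read —
#' integer STRING combined scores (0-999) are not rescaled.
#'
#' @param path path to a TSV file with at least three columns: two node IDs
#'   and a numeric weight. A single header line is tolerated and skipped when
#'   its weight field is non-numeric.
#' @param weight_column for files with a header, name of the weight column;
#'   defaults to the third column.
#' @return an undirected `igraph` graph with vertex attribute `name` and edge
#'   attribute `weight`.
#' @export
read_edge_list <- function(path, weight_column = NULL) {
  tab <- read_tsv_table(path, 3L, "edge list")
  fields <- tab$fields
  lineno <- tab$lineno
  wcol <- 3L
  # header detection: first row's candidate weight field is non-numeric
  header <- fields[[1]]
  if (is.na(suppressWarnings(as.numeric(header[wcol])))) {
    if (!is.null(weight_column)) {
      wcol <- match(weight_column, header)
      if (is.na(wcol)) stopf("edge list: no column named '%s'", weight_column)
    }
    fields <- fields[-1]
    lineno <- lineno[-1]
    if (length(fields) == 0L) stopf("edge list: no data rows in %s", path)
  }
  a <- vapply(fields, `[`, "", 1L)
  b <- vapply(fields, `[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(fields, `[`, "", wcol)))
  if (anyNA(w)) {
    stopf("edge list: non-numeric weight on line %d", lineno[which(is.na(w))[1]])
  }
  ppi_graph(data.frame(a = a, b = b, weight = w, stringsAsFactors = FALSE))
}

#' Build a PPI graph from an edge data frame
#'
#' @param edges data.frame with columns `a`, `b`, `weight`.
#' @return undirected weighted `igraph` graph (self-loops dropped, duplicate
#'   pairs collapsed to the maximum weight).
#' @export
ppi_graph <- function(edges) {
  stopifnot(all(c("a", "b", "weight") %in% names(edges)))
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  loops <- edges$a == edges$b
  if (any(loops)) {
    message(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  u <- pmin(edges$a, edges$b)
  v <- pmax(edges$a, edges$b)
  key <- paste(u, v, sep = "\r")
  w <- tapply(edges$weight, key, max)
  uv <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  if (is.null(uv)) {
    g <- igraph::make_empty_graph(directed = FALSE)
  } else {
    df <- data.frame(from = uv[, 1], to = uv[, 2], weight = as.numeric(w),
                     stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(df, directed = FALSE)
  }
  stopifnot(all(is.finite(igraph::E(g)$weight)))
  g
}

#' Write a weighted edge list as TSV
#'
#' @param g undirected weighted `igraph` graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_data_frame(g, what = "edges")
  u <- pmin(el$from, el$to)
  v <- pmax(el$from, el$to)
  out <- data.frame(protein_a = u, protein_b = v, weight = el$weight)
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-to-GO annotation table
#'
#' GAF-like TSV with columns `protein_id`, `go_id`, `aspect` where the aspect
#' is one of `BP`, `MF`, `CC`. Duplicated triples are collapsed.
#'
#' @param path TSV path (optional header line is skipped).
#' @return an [annotation_table].
#' @export
read_annotations <- function(path) {
  tab <- read_tsv_table(path, 3L, "annotations")
  fields <- tab$fields
  lineno <- tab$lineno
  if (identical(toupper(fields[[1]][3]), "ASPECT")) {
    fields <- fields[-1]
    lineno <- lineno[-1]
  }
  if (length(fields) == 0L) stopf("annotations: no data rows in %s", path)
  aspect <- vapply(fields, `[`, "", 3L)
  bad <- !(aspect %in% c("BP", "MF", "CC"))
  if (any(bad)) {
    stopf("annotations: unknown aspect '%s' on line %d",
          aspect[bad][1], lineno[bad][1])
  }
  annotation_table(data.frame(
    protein_id = vapply(fields, `[`, "", 1L),
    go_id = vapply(fields, `[`, "", 2L),
    aspect = aspect,
    stringsAsFactors = FALSE
  ))
}

#' Write an annotation table as TSV
#' @param tab an [annotation_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(tab, path) {
  df <- as.data.frame(tab)[order(tab$protein_id, tab$go_id, tab$aspect), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read amino-acid sequences from FASTA
#'
#' Sequences are uppercased and validated against the 20 canonical amino-acid
#' letters; any other character is a parse error naming the record, character
#' and position.
#'
#' @param path FASTA path (multi-line records allowed).
#' @return named character vector, names are record IDs (first whitespace
#'   token of the header).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("FASTA: no records in %s", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  for (i in seq_along(seqs)) {
    validate_sequence(seqs[[i]], names(seqs)[i])
  }
  seqs
}

#' Validate one amino-acid sequence
#' @param seq character scalar.
#' @param id record id used in error messages.
#' @return `seq`, invisibly.
#' @export
validate_sequence <- function(seq, id = "sequence") {
  if (!nzchar(seq)) stopf("%s: empty sequence", id)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad) > 0L) {
    stopf("%s: invalid amino-acid character '%s' at position %d",
          id, chars[bad[1]], bad[1])
  }
  invisible(seq)
}

#' Write sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a two-column ID-mapping table
#'
#' One-to-many mappings are allowed in both directions; duplicate pairs are
#' collapsed. Lookups of absent IDs yield an empty vector, never an error.
#'
#' @param path TSV with columns source_id, target_id (optional header).
#' @param direction free-text label describing the mapping direction.
#' @return an object of class `idmap`.
#' @export
read_mapping <- function(path, direction = "source->target") {
  tab <- read_tsv_table(path, 2L, "id map")
  fields <- tab$fields
  src <- vapply(fields, `[`, "", 1L)
  dst <- vapply(fields, `[`, "", 2L)
  if (identical(tolower(src[1]), "source_id")) {
    src <- src[-1]
    dst <- dst[-1]
  }
  idmap(src, dst, direction)
}

#' Construct an ID map
#' @param source_id,target_id character vectors of equal length.
#' @param direction free-text direction label.
#' @return object of class `idmap` (a de-duplicated pair table).
#' @export
idmap <- function(source_id, target_id, direction = "source->target") {
  df <- unique(data.frame(source_id = as.character(source_id),
                          target_id = as.character(target_id),
                          stringsAsFactors = FALSE))
  structure(df, direction = direction, class = c("idmap", "data.frame"))
}

#' Look up all targets of an ID
#' @param map an `idmap`.
#' @param ids character vector of source IDs.
#' @return character vector of mapped target IDs (unique, possibly empty).
#' @export
idmap_lookup <- function(map, ids) {
  if (is.null(map)) return(unique(as.character(ids)))
  unique(map$target_id[map$source_id %in% ids])
}

#' Write an ID map as TSV
#' @param map an `idmap`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(map, path) {
  df <- as.data.frame(map)[order(map$source_id, map$target_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the domain tables
#'
#' @param protein_domains_path TSV `protein_id domain_id`.
#' @param ddi_path TSV `domain_a domain_b` (DOMINE-style, order-insensitive).
#' @param domain_go_path optional TSV `domain_id go_id`.
#' @return object of class `domain_tables` with elements `protein_domains`,
#'   `ddi` (canonical: lexicographically smaller domain first) and
#'   `domain_go`.
#' @export
read_domain_tables <- function(protein_domains_path, ddi_path,
                               domain_go_path = NULL) {
  pd <- read_tsv_table(protein_domains_path, 2L, "protein domains")$fields
  pd <- data.frame(protein_id = vapply(pd, `[`, "", 1L),
                   domain_id = vapply(pd, `[`, "", 2L),
                   stringsAsFactors = FALSE)
  if (identical(tolower(pd$protein_id[1]), "protein_id")) pd <- pd[-1, ]
  dd <- read_tsv_table(ddi_path, 2L, "ddi")$fields
  dd <- data.frame(a = vapply(dd, `[`, "", 1L),
                   b = vapply(dd, `[`, "", 2L), stringsAsFactors = FALSE)
  if (identical(tolower(dd$a[1]), "domain_a")) dd <- dd[-1, ]
  dg <- NULL
  if (!is.null(domain_go_path)) {
    dg <- read_tsv_table(domain_go_path, 2L, "domain go")$fields
    dg <- data.frame(domain_id = vapply(dg, `[`, "", 1L),
                     go_id = vapply(dg, `[`, "", 2L), stringsAsFactors = FALSE)
    if (identical(tolower(dg$domain_id[1]), "domain_id")) dg <- dg[-1, ]
  }
  domain_tables(pd, dd, dg)
}

#' Construct domain tables
#' @param protein_domains data.frame `protein_id`, `domain_id`.
#' @param ddi data.frame of two domain-id columns (stored canonically).
#' @param domain_go optional data.frame `domain_id`, `go_id`.
#' @return object of class `domain_tables`.
#' @export
domain_tables <- function(protein_domains, ddi, domain_go = NULL) {
  pd <- unique(data.frame(protein_id = as.character(protein_domains[[1]]),
                          domain_id = as.character(protein_domains[[2]]),
                          stringsAsFactors = FALSE))
  a <- as.character(ddi[[1]])
  b <- as.character(ddi[[2]])
  dd <- unique(data.frame(domain_a = pmin(a, b), domain_b = pmax(a, b),
                          stringsAsFactors = FALSE))
  dg <- if (is.null(domain_go) || nrow(domain_go) == 0L) {
    data.frame(domain_id = character(0), go_id = character(0),
               stringsAsFactors = FALSE)
  } else {
    unique(data.frame(domain_id = as.character(domain_go[[1]]),
                      go_id = as.character(domain_go[[2]]),
                      stringsAsFactors = FALSE))
  }
  structure(list(protein_domains = pd, ddi = dd, domain_go = dg),
            class = "domain_tables")
}

#' Write domain tables as three TSV files
#' @param tables a `domain_tables` object.
#' @param protein_domains_path,ddi_path,domain_go_path output paths.
#' @return invisibly, the three paths.
#' @export
write_domain_tables <- function(tables, protein_domains_path, ddi_path,
                                domain_go_path) {
  wt <- function(df, path) {
    utils::write.table(df[do.call(order, df), , drop = FALSE], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(tables$protein_domains, protein_domains_path)
  wt(tables$ddi, ddi_path)
  wt(tables$domain_go, domain_go_path)
  invisible(c(protein_domains_path, ddi_path, domain_go_path))
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment with match = 1, mismatch = 0 and linear
#' gap penalty -1; identity is the number of matched positions divided by the
#' alignment length (gaps count in the denominator).
#'
#' @param a,b amino-acid sequences (character scalars).
#' @return identity in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  validate_sequence(a, "query")
  validate_sequence(b, "reference")
  mat <- matrix(0L, length(AA_ALPHABET), length(AA_ALPHABET),
                dimnames = list(AA_ALPHABET, AA_ALPHABET))
  diag(mat) <- 1L
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1,
    type = "global")
  nm <- Biostrings::nmatch(aln)
  # with match 1 / mismatch 0 / gap -1: gap columns = nmatch - score, so the
  # alignment length is nmatch + nmismatch + (nmatch - score)
  aln_len <- 2 * nm + Biostrings::nmismatch(aln) - Biostrings::score(aln)
  nm / aln_len
}

#' Map an ID with a sequence-identity fallback
#'
#' Returns the ID-map hits when present. Otherwise aligns the query sequence
#' against every reference and returns all reference IDs whose global
#' identity is at least `min_identity` (inclusive), sorted by identity
#' descending then ID ascending. With no map hit and no query sequence the
#' ID is unmappable and an empty vector is returned.
#'
#' @param query_id ID to map.
#' @param map an `idmap` (or `NULL`).
#' @param query_seq optional query sequence.
#' @param reference_seqs optional named character vector of reference
#'   sequences.
#' @param min_identity identity threshold, default 0.90.
#' @return character vector of target IDs (possibly empty).
#' @export
map_with_identity_fallback <- function(query_id, map, query_seq = NULL,
                                       reference_seqs = NULL,
                                       min_identity = 0.90) {
  hits <- if (is.null(map)) character(0) else
    unique(map$target_id[map$source_id == query_id])
  if (length(hits) > 0L) return(hits)
  if (is.null(query_seq) || is.null(reference_seqs) ||
      length(reference_seqs) == 0L) {
    return(character(0))
  }
  ident <- vapply(reference_seqs, function(r) seq_identity(query_seq, r),
                  numeric(1))
  keep <- ident >= min_identity
  ids <- names(reference_seqs)[keep]
  ids[order(-ident[keep], ids)]
}
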