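#' Read a featureCounts-style gene count table
#'
#' Reads a TSV with one row per gene-level feature, a `Length` column
#' (case-insensitive) giving feature length in base pairs, and one integer
#' count column per sample. The optional featureCounts columns `Chr`,
#' `Start`, `End` and `Strand` are tolerated and ignored.
#'
#' @param path Path to the TSV file.
#' @param layer Omic layer of the counts, `"MG"` (metagenomic, DNA) or
#'   `"MT"` (metatranscriptomic, RNA).
#' @return A `gene_feature_table`: list with integer matrix `counts`
#'   (features x samples), integer vector `length_bp` named by feature, and
#'   `layer`.
#' @export
read_counts <- function(path, layer = c("MG", "MT")) {
  layer <- match.arg(layer)
  if (!file.exists(path)) stop_fmt("count file '%s' does not exist", path)
  if (file.size(path) == 0L) stop_fmt("count file '%s' is empty", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_fmt("count file '%s' contains no feature rows", path)
  id_col <- names(df)[1L]
  drop <- tolower(names(df)) %in% c("chr", "start", "end", "strand")
  len_col <- which(tolower(names(df)) == "length")
  if (length(len_col) == 0L)
    stop_fmt("count file '%s' has no 'Length' column", path)
  len_col <- len_col[1L]
  ids <- as.character(df[[id_col]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop_fmt("duplicate feature id(s) in '%s': %s", path,
             paste(unique(dup), collapse = ", "))
  lens <- df[[len_col]]
  if (any(!is.finite(lens)) || any(lens < 1) || any(lens != round(lens)))
    stop_fmt("lengths in '%s' must be integers >= 1", path)
  keep <- setdiff(seq_along(df), c(1L, len_col, which(drop)))
  if (length(keep) == 0L) stop_fmt("count file '%s' has no sample columns", path)
  cm <- as.matrix(df[, keep, drop = FALSE])
  storage.mode(cm) <- "double"
  if (any(!is.finite(cm)) || any(cm < 0) || any(cm != round(cm)))
    stop_fmt("counts in '%s' must be non-negative integers", path)
  storage.mode(cm) <- "integer"
  rownames(cm) <- ids
  gene_feature_table(cm, stats::setNames(as.integer(lens), ids), layer)
}

#' Construct a validated gene feature table
#'
#' @param counts Integer matrix, features x samples, with dimnames.
#' @param length_bp Integer vector of feature lengths named by feature id.
#' @param layer `"MG"` or `"MT"`.
#' @return A `gene_feature_table` object.
#' @export
gene_feature_table <- function(counts, length_bp, layer = c("MG", "MT")) {
  layer <- match.arg(layer)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_fmt("counts must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_fmt("duplicate feature ids in counts")
  if (!all(rownames(counts) %in% names(length_bp)))
    stop_fmt("every feature needs a length")
  length_bp <- length_bp[rownames(counts)]
  if (any(length_bp < 1)) stop_fmt("all feature lengths must be >= 1")
  if (any(counts < 0)) stop_fmt("counts must be non-negative")
  structure(list(counts = counts, length_bp = length_bp, layer = layer),
            class = "gene_feature_table")
}

#' @export
print.gene_feature_table <- function(x, ...) {
  cat(sprintf("gene_feature_table [%s]: %d features x %d samples\n",
              x$layer, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Write a gene feature table as featureCounts-style TSV
#' @param table A `gene_feature_table`.
#' @param path Output path.
#' @export
write_counts <- function(table, path) {
  df <- data.frame(Geneid = rownames(table$counts),
                   Length = as.integer(table$length_bp),
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature annotation table
#'
#' TSV with columns `feature_id`, `ko_id`, `lineage`. Lineage strings may be
#' GTDB style (`d__...;p__...;...;s__...`) or plain semicolon-separated ranks;
#' genus and species are extracted by rank position with prefix stripping.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns feature_id, ko_id, lineage, genus, species.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("feature_id", "ko_id", "lineage")
  if (!all(need %in% names(df)))
    stop_fmt("annotation file must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$feature_id))
    stop_fmt("duplicate feature ids in annotation file")
  df$ko_id[df$ko_id == ""] <- NA_character_
  df$lineage[df$lineage == ""] <- NA_character_
  tax <- parse_lineage(df$lineage)
  df$genus <- tax$genus
  df$species <- tax$species
  df
}

#' Parse taxonomy lineage strings into genus and species
#'
#' Accepts GTDB-style prefixed ranks (`d__;p__;c__;o__;f__;g__;s__`) and plain
#' semicolon-separated rank lists (domain to species, genus 6th, species 7th).
#'
#' @param lineage Character vector of lineage strings (NA allowed).
#' @return data.frame with columns genus and species.
#' @export
parse_lineage <- function(lineage) {
  genus <- species <- rep(NA_character_, length(lineage))
  for (i in seq_along(lineage)) {
    l <- lineage[i]
    if (is.na(l) || !nzchar(l)) next
    parts <- trimws(strsplit(l, ";", fixed = TRUE)[[1L]])
    pref <- grepl("^[a-z]__", parts)
    if (any(pref)) {
      g <- sub("^g__", "", parts[grepl("^g__", parts)])
      s <- sub("^s__", "", parts[grepl("^s__", parts)])
      if (length(g) && nzchar(g[1L])) genus[i] <- g[1L]
      if (length(s) && nzchar(s[1L])) species[i] <- s[1L]
    } else {
      if (length(parts) >= 6L && nzchar(parts[6L])) genus[i] <- parts[6L]
      if (length(parts) >= 7L && nzchar(parts[7L])) species[i] <- parts[7L]
    }
  }
  data.frame(genus = genus, species = species, stringsAsFactors = FALSE)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id` and `group` (levels HC and PD); extra columns
#' are carried along as covariates.
#'
#' @param path Path to the TSV file.
#' @return data.frame keyed by unique sample_id.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop_fmt("metadata must have columns sample_id and group")
  if (anyDuplicated(df$sample_id)) stop_fmt("duplicate sample ids in metadata")
  bad <- setdiff(unique(df$group), c("HC", "PD"))
  if (length(bad) > 0L)
    stop_fmt("metadata group must be HC or PD; found: %s", paste(bad, collapse = ", "))
  df
}

#' Intersect samples across MG, MT and metadata
#'
#' The MT/MG ratio needs paired layers, so the analysis sample set is the
#' intersection of the two count tables and the metadata; every dropped sample
#' is reported with a log line.
#'
#' @param mg,mt `gene_feature_table` objects.
#' @param meta Metadata data.frame.
#' @return list(mg, mt, meta) restricted to the shared samples, original order
#'   of the MG table preserved.
#' @export
align_samples <- function(mg, mt, meta) {
  shared <- intersect(intersect(colnames(mg$counts), colnames(mt$counts)),
                      meta$sample_id)
  if (length(shared) == 0L) stop_fmt("no samples shared across MG, MT and metadata")
  all_ids <- unique(c(colnames(mg$counts), colnames(mt$counts), meta$sample_id))
  for (s in setdiff(all_ids, shared))
    log_msg("sample '%s' dropped: not present in all of MG, MT, metadata", s)
  shared <- colnames(mg$counts)[colnames(mg$counts) %in% shared]
  mg$counts <- mg$counts[, shared, drop = FALSE]
  mt$counts <- mt$counts[, shared, drop = FALSE]
  meta <- meta[match(shared, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(mg = mg, mt = mt, meta = meta)
}

#' Read gene sets in GMT format
#'
#' One set per line: name TAB description TAB member ids. Members are
#' de-duplicated within a set; duplicate set names are an error.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of member ids, with a
#'   `description` attribute (named character vector).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_fmt("GMT file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_fmt("GMT file '%s' is empty", path)
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop_fmt("GMT line %d has %d field(s); need name, description, members",
               i, length(f))
    nm <- f[1L]
    if (nm %in% names(sets)) stop_fmt("duplicate gene set name '%s' (line %d)", nm, i)
    members <- unique(f[-c(1L, 2L)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) stop_fmt("gene set '%s' (line %d) has no members", nm, i)
    sets[[nm]] <- members
    descs[nm] <- f[2L]
  }
  attr(sets, "description") <- descs
  sets
}

#' Export a co-expression network as a weighted edge list and module table
#'
#' Writes an undirected weighted edge-list TSV of all adjacency entries above
#' `threshold`, a node table (so nodes survive even with zero edges), a
#' lossless module-assignment TSV, and optionally GraphML.
#'
#' @param net A `coexpression_network` (see [signed_adjacency()]).
#' @param partition Optional `module_partition`; when given the module TSV is
#'   written next to the edge list.
#' @param path Base path; files `<path>_edges.tsv`, `<path>_nodes.tsv`,
#'   `<path>_modules.tsv` (and `<path>.graphml`) are created.
#' @param threshold Minimum adjacency weight for an edge to be exported.
#' @param graphml Also write GraphML via igraph.
#' @return Invisibly, the vector of files written.
#' @export
write_network <- function(net, path, partition = NULL, threshold = 0,
                          graphml = FALSE) {
  a <- net$adjacency
  genes <- rownames(a)
  idx <- which(upper.tri(a) & a > threshold, arr.ind = TRUE)
  edges <- data.frame(from = genes[idx[, 1L]], to = genes[idx[, 2L]],
                      weight = a[idx], stringsAsFactors = FALSE)
  files <- character(0)
  f_e <- paste0(path, "_edges.tsv")
  utils::write.table(edges, f_e, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f_e)
  f_n <- paste0(path, "_nodes.tsv")
  utils::write.table(data.frame(gene = genes, stringsAsFactors = FALSE),
                     f_n, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f_n)
  if (!is.null(partition)) {
    f_m <- paste0(path, "_modules.tsv")
    write_module_assignments(partition, f_m)
    files <- c(files, f_m)
  }
  if (graphml) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = genes))
    f_g <- paste0(path, ".graphml")
    igraph::write_graph(g, f_g, format = "graphml")
    files <- c(files, f_g)
  }
  invisible(files)
}

#' Write module assignments to TSV
#' @param partition A `module_partition`.
#' @param path Output path.
#' @export
write_module_assignments <- function(partition, path) {
  df <- data.frame(gene = names(partition$labels),
                   module = unname(partition$labels),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read module assignments written by [write_module_assignments()]
#' @param path Path to the TSV.
#' @return Named character vector gene -> module label.
#' @export
read_module_assignments <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(df$module, df$gene)
}
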