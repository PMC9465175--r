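# Circular-coordinate data model and I/O for genomes and annotations.
#
# Coordinates are 1-based inclusive throughout. A feature that spans the
# circular origin is encoded with start > end; genome_length is required
# wherever wrap arithmetic happens.

#' Construct a genome record
#'
#' @param id sequence identifier.
#' @param seq nucleotide string over `{A,C,G,T,N}` (upper-cased, `U` mapped
#'   to `T`).
#' @param circular is the molecule circular? Mitogenomes are.
#' @return an object of class `GenomeRecord`: a list with `id`, `seq`,
#'   `circular` and `length`.
#' @export
genome_record <- function(id, seq, circular = TRUE) {
  seq <- chartr("u", "t", toupper(seq))
  seq <- chartr("U", "T", seq)
  if (nchar(seq) == 0L) stop("empty sequence for record '", id, "'")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop("non-IUPAC character '", substr(seq, bad, bad),
         "' at position ", bad, " in record '", id, "'")
  }
  structure(list(id = as.character(id), seq = seq,
                 circular = isTRUE(circular), length = nchar(seq)),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord '%s': %d bp, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Construct a feature annotation
#'
#' @param name feature name (e.g. `cox1`, `trnL2(UUR)`, `A+T-rich region`).
#' @param gene_class one of `"PCG"`, `"tRNA"`, `"rRNA"`, `"control_region"`.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive coordinates; `start > end` encodes a
#'   feature wrapping the circular origin.
#' @param anticodon optional anticodon triplet (tRNAs).
#' @param start_codon,stop_codon optional codon annotations (PCGs).
#' @return an object of class `FeatureAnnotation`.
#' @export
feature_annotation <- function(name, gene_class, strand, start, end,
                               anticodon = NA_character_,
                               start_codon = NA_character_,
                               stop_codon = NA_character_) {
  gene_class <- match.arg(gene_class, c("PCG", "tRNA", "rRNA", "control_region"))
  strand <- match.arg(strand, c("+", "-"))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < 1L)
    stop("invalid coordinates for feature '", name, "'")
  structure(list(name = as.character(name), gene_class = gene_class,
                 strand = strand, start = start, end = end,
                 anticodon = as.character(anticodon),
                 start_codon = as.character(start_codon),
                 stop_codon = as.character(stop_codon)),
            class = "FeatureAnnotation")
}

feature_wraps <- function(f) f$start > f$end

#' Construct an annotation table
#'
#' Features are stored in circular order (ascending start, ties broken by
#' end). The printed intergenic-nucleotide and size columns of a published
#' table can be retained verbatim alongside the coordinates.
#'
#' @param genome_id genome identifier the features belong to.
#' @param genome_length genome length in bp.
#' @param features list of [feature_annotation()] objects.
#' @param ign optional integer vector parallel to `features`: a printed
#'   intergenic-nucleotide column (negative = overlap), `NA` where blank.
#' @param size_printed optional integer vector parallel to `features`: a
#'   printed size column (sizes are otherwise computed from coordinates).
#' @return an object of class `AnnotationTable`.
#' @export
annotation_table <- function(genome_id, genome_length, features,
                             ign = NULL, size_printed = NULL) {
  stopifnot(length(features) >= 1L)
  nm <- vapply(features, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate gene name: ", nm[duplicated(nm)][1L])
  genome_length <- as.integer(genome_length)
  for (f in features) {
    if (f$start > genome_length || f$end > genome_length)
      stop("feature '", f$name, "' exceeds genome length ", genome_length)
  }
  ord <- order(vapply(features, `[[`, integer(1), "start"),
               vapply(features, `[[`, integer(1), "end"))
  features <- features[ord]
  if (!is.null(ign)) {
    if (length(ign) != length(features))
      stop("ign must be parallel to features")
    ign <- as.integer(ign)[ord]
  }
  if (!is.null(size_printed)) {
    if (length(size_printed) != length(features))
      stop("size_printed must be parallel to features")
    size_printed <- as.integer(size_printed)[ord]
  }
  structure(list(genome_id = as.character(genome_id),
                 genome_length = genome_length,
                 features = features, ign = ign,
                 size_printed = size_printed),
            class = "AnnotationTable")
}

#' @export
print.AnnotationTable <- function(x, ...) {
  cat(sprintf("AnnotationTable for '%s' (%d bp): %d features\n",
              x$genome_id, x$genome_length, length(x$features)))
  invisible(x)
}

#' Coerce an annotation table to a data frame
#'
#' @param x an `AnnotationTable`.
#' @param ... unused.
#' @return one row per feature with name, class, strand, coordinates and,
#'   when present, the printed size and IGN columns.
#' @method as.data.frame AnnotationTable
#' @export
as.data.frame.AnnotationTable <- function(x, ...) {
  d <- data.frame(
    name = vapply(x$features, `[[`, character(1), "name"),
    gene_class = vapply(x$features, `[[`, character(1), "gene_class"),
    strand = vapply(x$features, `[[`, character(1), "strand"),
    start = vapply(x$features, `[[`, integer(1), "start"),
    end = vapply(x$features, `[[`, integer(1), "end"),
    anticodon = vapply(x$features, `[[`, character(1), "anticodon"),
    start_codon = vapply(x$features, `[[`, character(1), "start_codon"),
    stop_codon = vapply(x$features, `[[`, character(1), "stop_codon"),
    stringsAsFactors = FALSE)
  if (!is.null(x$size_printed)) d$size_printed <- x$size_printed
  if (!is.null(x$ign)) d$ign_printed <- x$ign
  d
}

get_feature <- function(table, name) {
  for (f in table$features) if (f$name == name) return(f)
  stop("feature '", name, "' not found in annotation table")
}

#' Read a multi-record FASTA file
#'
#' @param path FASTA file.
#' @param circular mark records circular (default `TRUE`; mitogenomes).
#' @return list of [genome_record()] objects in input order.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  # read as raw strings: genome_record() normalizes case, maps U to T and
  # validates the alphabet (readDNAStringSet would silently drop U)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  lapply(seq_along(ss), function(i)
    genome_record(ids[i], as.character(ss[[i]]), circular = circular))
}

#' Write genome records to FASTA
#'
#' @param records a `GenomeRecord` or list of them.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "GenomeRecord")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    starts <- seq(1L, r$length, by = width)
    writeLines(substring(r$seq, starts, pmin(starts + width - 1L, r$length)), con)
  }
  invisible(path)
}

# ---- Table-2-dialect feature table ------------------------------------------

TABLE2_HEADER <- c("Gene", "Direction", "Location", "Size (bp)", "Anticodon",
                   "Start codon", "Stop codon", "Intergenic Nucleotides *")

infer_gene_class <- function(name) {
  lo <- tolower(name)
  if (grepl("^trn", lo)) "tRNA"
  else if (grepl("^rrn", lo)) "rRNA"
  else if (grepl("rich region|d-loop|control", lo)) "control_region"
  else "PCG"
}

parse_location <- function(loc, label) {
  # accepts "1392-2925", "1392–2925" (en dash), thousands separators
  loc <- gsub(",", "", trimws(loc))
  parts <- strsplit(loc, "–|—|-")[[1]]
  parts <- parts[nzchar(parts)]
  nums <- suppressWarnings(as.integer(parts))
  if (length(nums) != 2L || anyNA(nums))
    stop("unparseable location '", loc, "' in row '", label, "'")
  nums
}

parse_signed_int <- function(x) {
  # accepts the Unicode minus sign
  x <- gsub("−", "-", trimws(x))
  x[x %in% c("", "—", "–", "-", "NA")] <- NA
  suppressWarnings(as.integer(x))
}

#' Read a Table-2-dialect feature table
#'
#' Tab-delimited with header columns Gene / Direction / Location / Size (bp) /
#' Anticodon / Start codon / Stop codon / Intergenic Nucleotides *. Locations
#' are `start-end` (hyphen or en dash, 1-based inclusive, thousands
#' separators permitted); the printed Size and IGN columns are retained
#' verbatim alongside sizes computed from coordinates.
#'
#' Two direction dialects are supported: `standard` (`+`/`-`) and `table2`,
#' where an em/en dash marks the heavy (plus) strand and `+` the light
#' (minus) strand — the convention of the published arrangement table.
#' `dialect = "auto"` (default) selects `table2` when any dash appears in
#' the Direction column.
#'
#' @param path TSV file.
#' @param genome_length genome length in bp (coordinates are validated
#'   against it).
#' @param genome_id identifier for the annotation table.
#' @param dialect `"auto"`, `"standard"` or `"table2"`.
#' @return an [annotation_table()] with printed `ign` and `size_printed`
#'   retained.
#' @export
read_feature_table <- function(path, genome_length, genome_id = "genome",
                               dialect = c("auto", "standard", "table2")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("Gene", "Direction", "Location")
  if (!all(need %in% names(d)))
    stop("feature table must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$Gene))
    stop("duplicate gene name: ", d$Gene[duplicated(d$Gene)][1L])
  dir_raw <- trimws(d$Direction)
  if (dialect == "auto") {
    dialect <- if (any(grepl("–|—", dir_raw))) "table2" else "standard"
  }
  strand <- if (dialect == "table2") {
    ifelse(dir_raw == "+", "-", "+")
  } else {
    ifelse(dir_raw == "-", "-", "+")
  }
  blank_to_na <- function(x) {
    x <- trimws(x)
    x[x %in% c("", "—", "–")] <- NA
    x
  }
  anticodon <- if ("Anticodon" %in% names(d)) blank_to_na(d$Anticodon) else NA
  startc <- if ("Start codon" %in% names(d)) blank_to_na(d$`Start codon`) else NA
  stopc <- if ("Stop codon" %in% names(d)) blank_to_na(d$`Stop codon`) else NA
  feats <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    se <- parse_location(d$Location[i], d$Gene[i])
    feats[[i]] <- feature_annotation(
      name = trimws(d$Gene[i]),
      gene_class = infer_gene_class(d$Gene[i]),
      strand = strand[i], start = se[1], end = se[2],
      anticodon = if (length(anticodon) > 1) anticodon[i] else NA,
      start_codon = if (length(startc) > 1) startc[i] else NA,
      stop_codon = if (length(stopc) > 1) stopc[i] else NA)
  }
  ign <- if ("Intergenic Nucleotides *" %in% names(d))
    parse_signed_int(d$`Intergenic Nucleotides *`) else NULL
  size_printed <- if ("Size (bp)" %in% names(d))
    parse_signed_int(d$`Size (bp)`) else NULL
  annotation_table(genome_id, genome_length, feats,
                   ign = ign, size_printed = size_printed)
}

#' Write an annotation table in the Table-2 dialect
#'
#' Emits the published column header byte-for-byte plus two extra columns,
#' `computed_size` and `computed_ign`, derived from the coordinates.
#'
#' @param table an `AnnotationTable`.
#' @param path output TSV.
#' @param dialect direction dialect to emit (see [read_feature_table()]).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, dialect = c("standard", "table2")) {
  dialect <- match.arg(dialect)
  rows <- build_arrangement(table)
  d <- as.data.frame(table)
  dir_out <- if (dialect == "table2")
    ifelse(d$strand == "+", "—", "+") else d$strand
  na_blank <- function(x) ifelse(is.na(x), "", as.character(x))
  out <- data.frame(
    Gene = d$name,
    Direction = dir_out,
    Location = paste0(d$start, "-", d$end),
    `Size (bp)` = na_blank(table$size_printed %||% rows$size),
    Anticodon = na_blank(d$anticodon),
    `Start codon` = na_blank(d$start_codon),
    `Stop codon` = na_blank(d$stop_codon),
    `Intergenic Nucleotides *` = na_blank(table$ign %||% rep(NA, nrow(d))),
    computed_size = rows$size,
    computed_ign = rows$ign_next,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a feature's nucleotide sequence
#'
#' Minus-strand features are reverse-complemented; features wrapping the
#' circular origin (`start > end`) concatenate the suffix and prefix before
#' strand handling, and require a circular genome.
#'
#' @param genome a [genome_record()].
#' @param f a [feature_annotation()], or anything with `start`, `end`,
#'   `strand` fields.
#' @return nucleotide string of length [feature_length()].
#' @export
extract_feature_sequence <- function(genome, f) {
  if (f$start > genome$length || f$end > genome$length)
    stop("feature '", f$name %||% "?", "' outside genome")
  s <- if (feature_wraps(f)) {
    if (!genome$circular)
      stop("feature wraps the origin but genome '", genome$id, "' is not circular")
    paste0(substr(genome$seq, f$start, genome$length),
           substr(genome$seq, 1L, f$end))
  } else {
    substr(genome$seq, f$start, f$end)
  }
  if (f$strand == "-") revcomp(s) else s
}

# ---- GenBank flat-file subset -----------------------------------------------

genbank_class_map <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                       misc_feature = "control_region",
                       D_loop = "control_region", `D-loop` = "control_region")

#' Read a GenBank flat file (subset)
#'
#' Parses LOCUS, the FEATURES keys `CDS`, `tRNA`, `rRNA`, `misc_feature` and
#' `D-loop` (locations `a..b`, `complement(a..b)` and an origin-spanning
#' `join(a..b,c..d)`), the `/gene`, `/product`, `/anticodon` qualifiers, and
#' the ORIGIN block.
#'
#' @param path GenBank flat file.
#' @return list with elements `genome` ([genome_record()]) and `table`
#'   ([annotation_table()]).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("missing LOCUS line in ", path)
  locus_id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  locus_len <- as.integer(sub(".*?(\\d+)\\s+bp.*", "\\1", locus[1]))
  circular <- grepl("circular", locus[1])

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("missing ORIGIN block in ", path)
  end <- grep("^//", lines)
  end <- if (length(end)) end[end > ori[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(end - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  genome <- genome_record(locus_id, seq, circular = circular)

  feat_start <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_start)) {
    block <- lines[(feat_start[1] + 1L):(ori[1] - 1L)]
    key_idx <- grep("^\\s{2,8}\\S", block)
    key_idx <- key_idx[!grepl("^\\s{10,}", block[key_idx])]
    for (k in seq_along(key_idx)) {
      i <- key_idx[k]
      j <- if (k < length(key_idx)) key_idx[k + 1] - 1L else length(block)
      key <- sub("^\\s+(\\S+).*", "\\1", block[i])
      if (!key %in% names(genbank_class_map)) next
      entry <- paste(gsub("^\\s+", "", block[i:j]), collapse = " ")
      loc <- sub("^\\S+\\s+(\\S+).*", "\\1", trimws(block[i]))
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      if (grepl("^join\\(", loc)) {
        segs <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
        b1 <- as.integer(strsplit(segs[1], "\\.\\.")[[1]])
        b2 <- as.integer(strsplit(segs[length(segs)], "\\.\\.")[[1]])
        start <- b1[1]; endc <- b2[2]
        if (!genome$circular || b1[1] <= b2[2])
          stop("unsupported join() location: ", loc)
      } else {
        b <- as.integer(strsplit(loc, "\\.\\.")[[1]])
        if (length(b) == 1L) b <- c(b, b)
        if (anyNA(b)) stop("unparseable location '", loc, "' in ", path)
        start <- b[1]; endc <- b[2]
      }
      if (max(start, endc) > locus_len)
        stop("feature beyond LOCUS length in ", path, ": ", loc)
      qual <- function(q) {
        m <- regmatches(entry, regexpr(paste0("/", q, '="[^"]*"'), entry))
        if (length(m)) sub(paste0("/", q, '="([^"]*)"'), "\\1", m) else NA_character_
      }
      nm <- qual("gene")
      if (is.na(nm)) nm <- qual("product")
      if (is.na(nm)) nm <- paste0(key, "_", start)
      feats[[length(feats) + 1L]] <- feature_annotation(
        name = nm, gene_class = unname(genbank_class_map[key]),
        strand = strand, start = start, end = endc,
        anticodon = qual("anticodon"))
    }
  }
  if (length(feats) == 0L) stop("no supported features found in ", path)
  list(genome = genome,
       table = annotation_table(genome$id, genome$length, feats))
}

#' Write a GenBank flat file (subset)
#'
#' The complement of [read_genbank()]: emits LOCUS, FEATURES and ORIGIN so
#' that reading the file back yields an equal genome and annotation table.
#'
#' @param genome a [genome_record()].
#' @param table an [annotation_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   INV",
                     genome$id, genome$length,
                     if (genome$circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s mitochondrial genome.", genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", genome$length), con)
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
              control_region = "D-loop")
  for (f in table$features) {
    loc <- if (feature_wraps(f))
      sprintf("join(%d..%d,1..%d)", f$start, genome$length, f$end)
    else sprintf("%d..%d", f$start, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-15s %s", key_of[f$gene_class], loc), con)
    writeLines(sprintf('                     /gene="%s"', f$name), con)
    if (!is.na(f$anticodon))
      writeLines(sprintf('                     /anticodon="%s"', f$anticodon), con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, genome$length, by = 60L)
  for (p in pos) {
    chunk <- substr(genome$seq, p, min(p + 59L, genome$length))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tolower(tens), collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
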