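# Minimal GenBank flat-file reader/writer covering the subset this
# package emits and consumes: a single circular record, CDS/rRNA/tRNA
# features with simple or complement() locations, and the /locus_tag,
# /product, /EC_number and /pseudo qualifiers. No installed R package
# parses GenBank flat files, so this is done in-repo.

#' Read a single-record GenBank flat file
#'
#' @param path GenBank flat file with one LOCUS record.
#' @return a [genome] object.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loc <- grep("^LOCUS", lines)
  if (length(loc) != 1L) stop("expected exactly one LOCUS record in ", path)
  toks <- strsplit(trimws(lines[loc]), "\\s+")[[1]]
  id <- toks[2]
  circular <- any(tolower(toks) == "circular")
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(fstart) || !length(ostart)) stop("missing FEATURES or ORIGIN block")

  # sequence
  seq_lines <- lines[(ostart + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  # features: key lines start at column 6, qualifiers at column 22
  feat_lines <- lines[(fstart + 1L):(ostart - 1L)]
  keys <- grepl("^ {5}\\S", feat_lines)
  idx <- which(keys)
  feats <- empty_features()
  for (j in seq_along(idx)) {
    i0 <- idx[j]
    i1 <- if (j < length(idx)) idx[j + 1L] - 1L else length(feat_lines)
    key <- sub("^\\s*(\\S+).*", "\\1", feat_lines[i0])
    if (!key %in% c("CDS", "rRNA", "tRNA")) next
    block <- feat_lines[i0:i1]
    locstr <- sub("^\\s*\\S+\\s+", "", block[1])
    # continuation lines of the location (no leading '/')
    k <- 2L
    while (k <= length(block) && !grepl("^\\s+/", block[k])) {
      locstr <- paste0(locstr, trimws(block[k])); k <- k + 1L
    }
    parsed <- parse_gb_location(locstr)
    quals <- parse_gb_qualifiers(block[k:length(block)])
    feats <- rbind(feats, data.frame(
      locus_tag = quals[["locus_tag"]] %||% sprintf("feat_%04d", j),
      type = key,
      start = parsed$start, end = parsed$end, strand = parsed$strand,
      pseudo = isTRUE(quals[[".pseudo"]]),
      product = quals[["product"]] %||% "",
      ec = quals[["EC_number"]] %||% "",
      stringsAsFactors = FALSE))
  }
  genome(id, seq, feats, is_circular = circular)
}

parse_gb_location <- function(x) {
  x <- gsub("[<>]", "", x)
  strand <- "+"
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  # join() of contiguous segments collapses to the covering interval here;
  # the simulator never emits origin-wrapping features
  x <- sub("^join\\((.*)\\)$", "\\1", x)
  nums <- as.integer(unlist(regmatches(x, gregexpr("[0-9]+", x))))
  list(start = min(nums), end = max(nums), strand = strand)
}

parse_gb_qualifiers <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  cur_name <- NULL
  cur_val <- NULL
  flush <- function() {
    if (!is.null(cur_name)) {
      v <- gsub("^\"|\"$", "", cur_val)
      if (cur_name == "pseudo") out[[".pseudo"]] <<- TRUE
      else if (cur_name == "EC_number" && !is.null(out[[cur_name]]))
        out[[cur_name]] <<- paste(out[[cur_name]], v, sep = ",")
      else out[[cur_name]] <<- v
    }
  }
  for (ln in lines) {
    if (grepl("^/", ln)) {
      flush()
      if (grepl("=", ln)) {
        cur_name <- sub("^/([^=]+)=.*$", "\\1", ln)
        cur_val <- sub("^/[^=]+=", "", ln)
      } else {
        cur_name <- sub("^/", "", ln)
        cur_val <- ""
      }
    } else {
      cur_val <- paste(cur_val, ln)
    }
  }
  flush()
  out
}

#' Write a genome as a GenBank flat file
#'
#' @param g a [genome].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_genbank <- function(g, path) {
  stopifnot(inherits(g, "genome"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s BCT 01-JAN-1980",
                     g$id, nchar(g$seq),
                     if (g$is_circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s, synthetic chromosome.", g$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  qual <- function(name, value) {
    sprintf("                     /%s=\"%s\"", name, value)
  }
  f <- g$features
  for (i in seq_len(nrow(f))) {
    locstr <- sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "-") locstr <- sprintf("complement(%s)", locstr)
    writeLines(sprintf("     %-16s%s", f$type[i], locstr), con)
    writeLines(qual("locus_tag", f$locus_tag[i]), con)
    if (nzchar(f$product[i])) writeLines(qual("product", f$product[i]), con)
    if (nzchar(f$ec[i]))
      for (ec in strsplit(f$ec[i], ",")[[1]])
        writeLines(qual("EC_number", ec), con)
    if (f$pseudo[i]) writeLines("                     /pseudo", con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(g$seq)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substring(s, p, min(p + 59L, nchar(s)))
    parts <- substring(chunk, seq(1L, nchar(chunk), 10L),
                       pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(parts, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
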