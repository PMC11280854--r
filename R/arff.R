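# ARFF export/import for Weka interoperability: 1044 numeric attributes
# named from the feature registry plus one nominal class attribute
# enumerating the dictionary. Nominal values are single-quoted so spaces and
# non-ASCII words survive.

arff_quote <- function(x) {
  paste0("'", gsub("'", "\\\\'", x), "'")
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  ok <- as.numeric(sprintf("%.15g", x)) == x
  out[ok] <- sprintf("%.15g", x[ok])
  out
}

#' Export a dataset's feature table to ARFF
#'
#' @param dataset a `sign_dataset` with a nonempty feature table
#' @param path output `.arff` file
#' @param relation relation name
#' @return `path`, invisibly
#' @export
export_arff <- function(dataset, path, relation = "signstream") {
  stopifnot(inherits(dataset, "sign_dataset"))
  if (is.null(dataset$features) || !nrow(dataset$features))
    stop_invalid("dataset has an empty feature table; nothing to export")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste("@relation", arff_quote(relation)), con)
  writeLines("", con)
  for (nm in colnames(dataset$features))
    writeLines(paste("@attribute", arff_quote(nm), "numeric"), con)
  writeLines(paste0("@attribute 'class' {",
                    paste(arff_quote(dataset$dictionary), collapse = ","),
                    "}"), con)
  writeLines("", con)
  writeLines("@data", con)
  rows <- apply(dataset$features, 1L, function(r)
    paste(fmt_num(r), collapse = ","))
  writeLines(paste0(rows, ",", arff_quote(dataset$labels)), con)
  invisible(path)
}

strip_quote <- function(x) {
  q <- grepl("^'.*'$", x)
  x[q] <- gsub("\\\\'", "'", substr(x[q], 2L, nchar(x[q]) - 1L))
  x
}

# Split on commas that are outside single quotes.
split_arff_fields <- function(line) {
  chars <- strsplit(line, "", fixed = TRUE)[[1L]]
  fields <- character(0)
  buf <- character(0)
  inq <- FALSE
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "\\" && inq && i < length(chars)) {
      buf <- c(buf, ch, chars[i + 1L]); i <- i + 2L; next
    }
    if (ch == "'") inq <- !inq
    if (ch == "," && !inq) { fields <- c(fields, paste(buf, collapse = "")); buf <- character(0) }
    else buf <- c(buf, ch)
    i <- i + 1L
  }
  c(fields, paste(buf, collapse = ""))
}

#' Read an ARFF file written by [export_arff()]
#'
#' Supports numeric attributes plus one final nominal class attribute (the
#' subset of ARFF this package writes).
#'
#' @param path `.arff` file
#' @return list with `relation`, `attributes` (data.frame name/type),
#'   `classes`, `features` (matrix) and `labels`
#' @export
read_arff <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lower <- tolower(lines)
  rel <- strip_quote(sub("^@relation\\s+", "", lines[grepl("^@relation", lower)][1L]))
  attr_lines <- lines[grepl("^@attribute", lower)]
  names_ <- character(0); types <- character(0); classes <- NULL
  for (al in attr_lines) {
    rest <- sub("^@attribute\\s+", "", al, ignore.case = TRUE)
    if (startsWith(rest, "'")) {
      end <- regexpr("'(?:[^'\\\\]|\\\\.)*'", rest, perl = TRUE)
      nm <- strip_quote(substr(rest, 1L, attr(end, "match.length")))
      ty <- trimws(substr(rest, attr(end, "match.length") + 1L, nchar(rest)))
    } else {
      sp <- regexpr("\\s", rest)
      nm <- substr(rest, 1L, sp - 1L)
      ty <- trimws(substr(rest, sp + 1L, nchar(rest)))
    }
    if (startsWith(ty, "{")) {
      inner <- sub("\\}\\s*$", "", sub("^\\{", "", ty))
      classes <- strip_quote(trimws(split_arff_fields(inner)))
      ty <- "nominal"
    }
    names_ <- c(names_, nm); types <- c(types, tolower(ty))
  }
  data_at <- which(lower == "@data")[1L]
  if (is.na(data_at)) stop_invalid("malformed ARFF: no @data section")
  rows <- lines[(data_at + 1L):length(lines)]
  parsed <- lapply(rows, split_arff_fields)
  nf <- length(names_) - 1L
  feats <- t(vapply(parsed, function(f) as.numeric(f[seq_len(nf)]),
                    numeric(nf)))
  colnames(feats) <- names_[seq_len(nf)]
  labels <- strip_quote(vapply(parsed, function(f) f[nf + 1L], ""))
  list(relation = rel,
       attributes = data.frame(name = names_, type = types,
                               stringsAsFactors = FALSE),
       classes = classes, features = feats, labels = labels)
}
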