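# Minimal CIF 1.1 reader/writer for the chem_comp component dialect and
# Monomer-Library restraint dialect: data_ blocks, key-value items,
# loop_ tables, quoted strings and semicolon text fields.  Not a general
# mmCIF engine; unknown constructs raise errors naming the line.

cifTokenizeLine <- function(line, lineno) {
  tokens <- character(0)
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      repeat {
        if (j > n) stop("unterminated quote on line ", lineno, call. = FALSE)
        nxt <- substr(line, j + 1L, j + 1L)
        # CIF rule: a quote closes only when followed by whitespace/EOL
        if (substr(line, j, j) == ch && (j == n || nxt %in% c(" ", "\t")))
          break
        j <- j + 1L
      }
      tokens <- c(tokens, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      tokens <- c(tokens, substr(line, i, j - 1L))
      i <- j
    }
  }
  tokens
}

# Tokenize full CIF text; semicolon text blocks collapse to one token.
cifTokenize <- function(lines) {
  tokens <- character(0); linenos <- integer(0)
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[[i]]
    if (startsWith(line, ";")) {
      buf <- substring(line, 2L)
      j <- i + 1L
      repeat {
        if (j > length(lines))
          stop("unterminated semicolon text field starting at line ", i,
               call. = FALSE)
        if (startsWith(lines[[j]], ";")) break
        buf <- c(buf, lines[[j]]); j <- j + 1L
      }
      tokens <- c(tokens, paste(buf, collapse = "\n"))
      linenos <- c(linenos, i)
      i <- j + 1L
    } else {
      tk <- cifTokenizeLine(line, i)
      tokens <- c(tokens, tk)
      linenos <- c(linenos, rep(i, length(tk)))
      i <- i + 1L
    }
  }
  list(tokens = tokens, linenos = linenos)
}

isCifTag <- function(x) startsWith(x, "_")
isCifReserved <- function(x) {
  lx <- tolower(x)
  startsWith(lx, "data_") || lx %in% c("loop_", "stop_", "global_") ||
    startsWith(lx, "save_")
}

# Parse CIF text into a list of blocks, each
# list(name, items = named character, loops = named list of data.frames
# keyed by category).  "." and "?" read as NA.
cifParse <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else text
  tk <- cifTokenize(lines)
  tokens <- tk$tokens; linenos <- tk$linenos
  blocks <- list(); cur <- NULL
  naify <- function(v) ifelse(v %in% c(".", "?"), NA_character_, v)
  i <- 1L
  flush <- function() if (!is.null(cur)) blocks[[length(blocks) + 1L]] <<- cur
  while (i <= length(tokens)) {
    t <- tokens[[i]]
    if (tolower(substr(t, 1, 5)) == "data_") {
      flush()
      cur <- list(name = substring(t, 6L), items = character(0),
                  loops = list())
      i <- i + 1L
    } else if (tolower(t) == "loop_") {
      if (is.null(cur))
        stop("loop_ outside a data block at line ", linenos[[i]],
             call. = FALSE)
      i <- i + 1L
      tags <- character(0)
      while (i <= length(tokens) && isCifTag(tokens[[i]])) {
        tags <- c(tags, tokens[[i]]); i <- i + 1L
      }
      if (!length(tags))
        stop("loop_ without tags at line ", linenos[[i - 1L]], call. = FALSE)
      vals <- character(0)
      while (i <= length(tokens) && !isCifTag(tokens[[i]]) &&
             !isCifReserved(tokens[[i]])) {
        vals <- c(vals, tokens[[i]]); i <- i + 1L
      }
      if (length(vals) %% length(tags) != 0L)
        stop("loop value count not a multiple of its ", length(tags),
             " tags (category ", tags[[1]], ")", call. = FALSE)
      cat_name <- sub("^_([^.]+)\\..*$", "\\1", tags[[1]])
      cols <- sub("^_[^.]+\\.", "", tags)
      m <- matrix(naify(vals), ncol = length(tags), byrow = TRUE)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- cols
      cur$loops[[cat_name]] <- df
    } else if (isCifTag(t)) {
      if (is.null(cur))
        stop("item outside a data block at line ", linenos[[i]],
             call. = FALSE)
      if (i + 1L > length(tokens) || isCifTag(tokens[[i + 1L]]) ||
          isCifReserved(tokens[[i + 1L]]))
        stop("item ", t, " has no value at line ", linenos[[i]],
             call. = FALSE)
      cur$items[[sub("^_", "", t)]] <- naify(tokens[[i + 1L]])
      i <- i + 2L
    } else {
      stop("unexpected token '", t, "' at line ", linenos[[i]],
           call. = FALSE)
    }
  }
  flush()
  blocks
}

# A category as a data.frame regardless of representation: loop_ form,
# or single-row key-value form (tags _cat.col).
cifCategory <- function(block, category) {
  if (!is.null(block$loops[[category]])) return(block$loops[[category]])
  pref <- paste0(category, ".")
  sel <- startsWith(names(block$items), pref)
  if (!any(sel)) return(NULL)
  vals <- block$items[sel]
  df <- as.data.frame(as.list(vals), stringsAsFactors = FALSE,
                      optional = TRUE)
  names(df) <- substring(names(block$items)[sel], nchar(pref) + 1L)
  df
}

cifQuote <- function(x) {
  x <- ifelse(is.na(x), ".", as.character(x))
  needs <- !nzchar(x) | grepl("[ \t'\"#]", x) | grepl("^[_$\\[\\]]", x) |
    tolower(x) %in% c("loop_", "stop_", "global_") |
    startsWith(tolower(x), "data_")
  ifelse(needs,
         ifelse(grepl("'", x, fixed = TRUE),
                paste0('"', x, '"'), paste0("'", x, "'")),
         x)
}

# Serialize one data block.  items: named character; loops: named list of
# data.frames keyed by category (all columns coerced to character).
cifWriteBlock <- function(name, items = character(0), loops = list()) {
  out <- c(paste0("data_", name))
  if (length(items)) {
    tags <- paste0("_", names(items))
    pad <- max(nchar(tags)) + 2L
    out <- c(out, paste0(formatC(tags, width = -pad), cifQuote(items)))
  }
  for (cat_name in names(loops)) {
    df <- loops[[cat_name]]
    if (is.null(df) || !nrow(df)) next
    out <- c(out, "loop_",
             paste0("_", cat_name, ".", names(df)))
    cols <- lapply(df, function(col) cifQuote(col))
    widths <- vapply(cols, function(c) max(nchar(c)), integer(1))
    rows <- do.call(paste, c(mapply(function(c, w) formatC(c, width = -w),
                                    cols, widths, SIMPLIFY = FALSE),
                             list(sep = " ")))
    out <- c(out, rows)
  }
  c(out, "")
}

# 17 significant digits: doubles survive a write/read round trip exactly
cifNum <- function(x) trimws(formatC(x, format = "g", digits = 17))
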