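# CHAT transcript parsing and fixed-length token encoding.
#
# Transcripts follow the CHAT coding standard (.cha): @-prefixed headers,
# *TIER: main lines (continuation lines start with a tab), %-prefixed
# dependent tiers. Parsing keeps the spoken word forms - including
# repetitions, which are clinically informative - and strips CHAT event and
# annotation markup.

#' Parsed CHAT transcript
#'
#' @slot subjectId subject identifier (file stem by default).
#' @slot utterances data.frame with columns \code{speaker} and \code{text},
#'   in document order.
#' @export
setClass("Transcript",
         representation(subjectId = "character", utterances = "data.frame"))

setValidity("Transcript", function(object) {
  u <- object@utterances
  if (!all(c("speaker", "text") %in% names(u))) {
    return("utterances needs speaker and text columns")
  }
  TRUE
})

#' @rdname Transcript-class
#' @param x a \code{Transcript}.
#' @export
setGeneric("utterances", function(x) standardGeneric("utterances"))

#' @rdname Transcript-class
#' @export
setMethod("utterances", "Transcript", function(x) x@utterances)

setMethod("show", "Transcript", function(object) {
  cat(sprintf("Transcript '%s': %d utterances (%s)\n", object@subjectId,
              nrow(object@utterances),
              paste(unique(object@utterances$speaker), collapse = ", ")))
})

# Strip CHAT inline markup from a main-line utterance, keeping spoken words.
.stripChatMarkup <- function(x) {
  x <- gsub("\x15[^\x15]*\x15", " ", x)          # time-alignment bullets
  x <- gsub("\\[[^][]*\\]", " ", x)              # [/], [//], [: text], [* ...]
  x <- gsub("&=\\S+", " ", x)                     # events e.g. &=laughs
  x <- gsub("&-?\\S+", " ", x)                    # fillers/phonological forms
  x <- gsub("\\+[<,^\"!?/.]+", " ", x)           # special terminators/links
  x <- gsub("\\((\\.+)\\)", " ", x)               # pause codes (.) (..) (...)
  x <- gsub("[<>]", " ", x)                       # retracing scope markers
  x <- gsub("[()]", "", x)                        # shortenings: (be)cause
  x <- gsub("(\\S+)@\\S+", "\\1", x)             # form markers: word@x
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Parse a CHAT (.cha) transcript
#'
#' Returns the utterances of the requested speaker tiers in document order,
#' with CHAT inline annotation (retracing markers, pause codes, events,
#' time-alignment bullets) stripped to plain words. Dependent tiers
#' (\code{\%mor}, \code{\%gra}, ...) are ignored.
#'
#' @param path path to a .cha file.
#' @param speakers character vector of tier codes to keep (default
#'   \code{"PAR"}, the participant). Use e.g. \code{c("PAR", "INV")} to also
#'   keep the investigator.
#' @param subjectId subject identifier; defaults to the file stem.
#' @return A \linkS4class{Transcript}; empty (0 utterances) if no line
#'   matches the requested tiers.
#' @export
parseChat <- function(path, speakers = "PAR", subjectId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L || !startsWith(lines[1L], "@")) {
    stop("CHAT parse error at line 1: expected @-header (e.g. @UTF8)")
  }
  spk <- character(0)
  txt <- character(0)
  cur <- NULL
  curSpk <- NULL
  flush <- function() {
    if (!is.null(cur) && curSpk %in% speakers) {
      spk <<- c(spk, curSpk)
      txt <<- c(txt, .stripChatMarkup(cur))
    }
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "*")) {
      flush()
      m <- regmatches(ln, regexec("^\\*([A-Za-z0-9]+):\\t?(.*)$", ln))[[1L]]
      if (length(m) != 3L) {
        stop("CHAT parse error at line ", i, ": malformed main tier line")
      }
      curSpk <- m[2L]
      cur <- m[3L]
    } else if (startsWith(ln, "\t") && !is.null(cur)) {
      cur <- paste(cur, trimws(ln))
    } else {
      flush() # header (@) or dependent tier (%) ends the utterance
    }
  }
  flush()
  if (is.null(subjectId)) {
    subjectId <- sub("\\.cha$", "", basename(path))
  }
  methods::new("Transcript", subjectId = subjectId,
               utterances = data.frame(speaker = spk, text = txt,
                                       stringsAsFactors = FALSE))
}

#' Fixed-length token encoding
#'
#' @slot tokenIds integer token ids, length exactly \code{maxLen}.
#' @slot padMask logical, TRUE at real-token positions; pad positions are
#'   contiguous at the end.
#' @slot maxLen encoding length (512 under the package defaults).
#' @export
setClass("TextEncoding",
         representation(tokenIds = "integer", padMask = "logical",
                        maxLen = "integer"))

setValidity("TextEncoding", function(object) {
  if (length(object@tokenIds) != object@maxLen) return("length != maxLen")
  if (length(object@padMask) != object@maxLen) return("mask length != maxLen")
  pads <- which(!object@padMask)
  if (length(pads) > 0L && !identical(pads, seq(min(pads), object@maxLen))) {
    return("pad positions must be contiguous at the end")
  }
  TRUE
})

#' @rdname TextEncoding-class
#' @param x a \code{TextEncoding}.
#' @export
setGeneric("tokenIds", function(x) standardGeneric("tokenIds"))

#' @rdname TextEncoding-class
#' @export
setMethod("tokenIds", "TextEncoding", function(x) x@tokenIds)

#' @rdname TextEncoding-class
#' @export
setGeneric("padMask", function(x) standardGeneric("padMask"))

#' @rdname TextEncoding-class
#' @export
setMethod("padMask", "TextEncoding", function(x) x@padMask)

setMethod("show", "TextEncoding", function(object) {
  cat(sprintf("TextEncoding: length %d, %d real tokens\n", object@maxLen,
              sum(object@padMask)))
})

# Special token ids of the package tokenizer.
PAD_ID <- 1L
CLS_ID <- 2L
SEP_ID <- 3L

# Deterministic polynomial hash of a word into [0, m)
.wordHash <- function(word, m) {
  h <- 0
  for (cc in utf8ToInt(word)) {
    h <- (h * 31 + cc) %% m
  }
  as.integer(h)
}

#' Tokenize text deterministically
#'
#' Lowercases, splits on whitespace with punctuation as separate tokens, and
#' maps each token to a stable id by a polynomial hash into a fixed
#' vocabulary. Ids 1..3 are reserved for [PAD], [CLS], [SEP].
#'
#' @param text character string.
#' @param vocabSize vocabulary size including the 3 specials.
#' @return integer vector of token ids (no specials added).
#' @export
tokenizeWords <- function(text, vocabSize = 8000L) {
  text <- tolower(text)
  text <- gsub("([[:punct:]])", " \\1 ", text)
  words <- strsplit(trimws(gsub("\\s+", " ", text)), " ")[[1L]]
  words <- words[nzchar(words)]
  if (length(words) == 0L) return(integer(0))
  vapply(words, .wordHash, integer(1L), m = vocabSize - 3L,
         USE.NAMES = FALSE) + 4L # ids in 4..vocabSize
}

#' Encode a transcript to a fixed-length token sequence
#'
#' Concatenates the utterance texts in order, tokenizes, wraps in
#' [CLS] ... [SEP], truncates the tail to fit and pads with [PAD] to exactly
#' \code{maxLen}.
#'
#' @param t a \linkS4class{Transcript} or character string.
#' @param maxLen output length (default 512); must be >= 2.
#' @param vocabSize tokenizer vocabulary size.
#' @return A \linkS4class{TextEncoding}.
#' @export
encodeText <- function(t, maxLen = 512L, vocabSize = 8000L) {
  if (maxLen < 2L) stop("maxLen must be >= 2 (room for [CLS] and [SEP])")
  text <- if (methods::is(t, "Transcript")) {
    paste(t@utterances$text, collapse = " ")
  } else {
    as.character(t)
  }
  ids <- tokenizeWords(text, vocabSize)
  keep <- min(length(ids), maxLen - 2L)
  ids <- c(CLS_ID, ids[seq_len(keep)], SEP_ID)
  nReal <- length(ids)
  ids <- c(ids, rep(PAD_ID, maxLen - nReal))
  methods::new("TextEncoding", tokenIds = as.integer(ids),
               padMask = seq_len(maxLen) <= nReal,
               maxLen = as.integer(maxLen))
}
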