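#' The four-point causality scale
#'
#' Both instruments in this package express their verdict on the same
#' four-level ordinal scale used throughout ADR causality assessment:
#' unlikely < possible < probable < definite.
#'
#' @return Character vector of the four category labels, in ordinal order.
#' @export
#' @examples
#' causality_levels()
causality_levels <- function() {
  c("unlikely", "possible", "probable", "definite")
}

#' Coerce to the causality scale
#'
#' Parses category tokens onto the ordered four-point scale. Tokens are
#' matched case-insensitively with surrounding whitespace stripped;
#' integer codes 1--4 (in ordinal order) are also accepted. Empty strings
#' and `NA` become missing values.
#'
#' @param x Character, factor or integer vector of category tokens.
#' @return An ordered factor with levels `causality_levels()`.
#' @export
#' @examples
#' as_causality(c("Definite ", "possible", NA, "3"))
as_causality <- function(x) {
  lv <- causality_levels()
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% 1:4)
    if (any(bad)) {
      stop("unknown causality code(s): ",
           paste(unique(x[bad]), collapse = ", "),
           " (expected 1-4)", call. = FALSE)
    }
    return(factor(lv[x], levels = lv, ordered = TRUE))
  }
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  low <- tolower(x)
  # numeric codes supplied as strings
  code <- suppressWarnings(as.integer(low))
  low[!is.na(code) & code %in% 1:4] <- lv[code[!is.na(code) & code %in% 1:4]]
  bad <- !is.na(low) & !(low %in% lv)
  if (any(bad)) {
    stop("unknown causality token(s): ",
         paste(sQuote(unique(x[bad])), collapse = ", "), call. = FALSE)
  }
  factor(low, levels = lv, ordered = TRUE)
}

# integer codes 1..4 on the fixed ordinal scale; NA preserved
causality_code <- function(x) {
  as.integer(as_causality(x))
}
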