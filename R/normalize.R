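#' Restore omitted measurement units
#'
#' Telegraphic descriptions often drop the unit from measurement lists
#' ("tibia/metatarsus: I, 0.42/0.32"), relying on a corpus-wide convention.
#' \code{add_units} makes such text self-contained: within each clause,
#' every maximal run of decimal measurement values (numbers with a decimal
#' point, chained by commas or slashes) that is not already followed by a
#' unit token gets the unit appended after its last value. Bare integers
#' (counts, indices) are never given a unit. The operation is idempotent
#' and changes nothing else.
#'
#' @param text character vector of description text.
#' @param unit unit token to insert (default \code{"mm"}).
#' @return The text with units restored.
#' @examples
#' add_units("tibia/metatarsus: I, 0.42/0.32")
#' @export
add_units <- function(text, unit = "mm") {
  # run = decimal number, then any number of (sep + decimal number);
  # skip when already followed by a unit token
  run <- "\\d+\\.\\d+(?:\\s*[,/]\\s*\\d+\\.\\d+)*"
  units_rx <- "(?:mm|cm|dm|m|um|µm)"
  pat <- paste0("(?<![\\d.])(", run, ")(?!\\d)(?!\\.\\d)",
                "(?!\\s*[,/]?\\s*\\d+\\.\\d)",
                "(?!\\s*", units_rx, "\\b)")
  vapply(text, function(s)
    gsub(pat, paste0("\\1 ", unit), s, perl = TRUE),
    "", USE.NAMES = FALSE)
}

#' Restore the omitted word "leg"
#'
#' Spider descriptions enumerate legs by bare Roman numerals ("I, 0.42/0.32
#' mm"). \code{add_leg} prefixes each bare upper-case Roman numeral I-IV
#' with \code{"leg "} when it occurs in measurement context, i.e. in a
#' sentence that carries decimal values, a measurement indicator, or a
#' colon-headed value list. Numerals already preceded by "leg" (any case)
#' are left alone; the operation is idempotent.
#'
#' @param text character vector of description text.
#' @param indicators measurement indicator terms that establish context.
#' @return The text with "leg" restored.
#' @examples
#' add_leg("tibia/metatarsus: I, 0.42/0.32 mm")
#' @export
add_leg <- function(text, indicators = measurement_indicators()) {
  ind_rx <- paste0("\\b(?:", paste(indicators, collapse = "|"), ")")
  vapply(text, function(s) {
    sent <- split_keep(s, "(?<=\\.)\\s+(?=[A-Z])")
    sent <- vapply(sent, function(x) {
      has_ctx <- grepl("\\d+\\.\\d+", x) || grepl(":", x, fixed = TRUE) ||
        grepl(ind_rx, x, ignore.case = TRUE, perl = TRUE)
      if (!has_ctx) return(x)
      gsub("(?<![Ll]eg )(?<![Ll]eg)\\b(IV|III|II|I)\\b(?!-)",
           "leg \\1", x, perl = TRUE)
    }, "")
    paste(sent, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# split s by a perl regex, keeping the delimiters attached to the left piece
split_keep <- function(s, rx) {
  m <- gregexpr(rx, s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(s)
  starts <- c(1L, m + attr(m, "match.length"))
  ends <- c(m + attr(m, "match.length") - 1L, nchar(s))
  substring(s, starts, ends)
}

#' Sanity-check description text before extraction
#'
#' Reports editing problems the user should fix before running the parser:
#' unmatched or mismatched brackets \code{()[]\{\}} with their character
#' positions, and non-ASCII hyphen/dash variants (en/em dashes, minus sign)
#' that should be converted to plain \code{"-"}.
#'
#' @param text a single description string.
#' @return A data frame with columns \code{kind}, \code{position},
#'   \code{message}; zero rows when the text is clean.
#' @export
preprocess_check <- function(text) {
  stopifnot(length(text) == 1L)
  issues <- data.frame(kind = character(), position = integer(),
                       message = character(), stringsAsFactors = FALSE)
  add <- function(kind, pos, msg)
    rbind(issues, data.frame(kind = kind, position = pos, message = msg,
                             stringsAsFactors = FALSE))
  chars <- strsplit(text, "")[[1]]
  openers <- c("(" = ")", "[" = "]", "{" = "}")
  stack_ch <- character(); stack_pos <- integer()
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% names(openers)) {
      stack_ch <- c(stack_ch, ch); stack_pos <- c(stack_pos, i)
    } else if (ch %in% openers) {
      hit <- which(openers[stack_ch] == ch)
      if (length(hit) && hit[length(hit)] == length(stack_ch)) {
        stack_ch <- stack_ch[-length(stack_ch)]
        stack_pos <- stack_pos[-length(stack_pos)]
      } else if (length(hit)) {
        # closes a deeper opener: the closer is mismatched and every
        # opener it skips over is unmatched
        k <- hit[length(hit)]
        issues <- add("bracket", i,
                      paste0("mismatched closing '", ch, "'"))
        for (j in seq(length(stack_ch), k + 1L))
          issues <- add("bracket", stack_pos[j],
                        paste0("unmatched opening '", stack_ch[j], "'"))
        stack_ch <- stack_ch[seq_len(k - 1L)]
        stack_pos <- stack_pos[seq_len(k - 1L)]
      } else {
        issues <- add("bracket", i,
                      paste0("unmatched closing '", ch, "'"))
      }
    }
  }
  if (length(stack_ch))
    for (k in seq_along(stack_ch))
      issues <- add("bracket", stack_pos[k],
                    paste0("unmatched opening '", stack_ch[k], "'"))
  dash <- gregexpr("[‐‑‒–—―−]", text)[[1]]
  if (dash[1] != -1L)
    for (p in as.integer(dash))
      issues <- add("hyphen", p,
                    "non-ASCII hyphen/dash variant; convert to '-'")
  issues[order(issues$position), , drop = FALSE]
}

#' Normalize a batch of description documents
#'
#' Convenience wrapper applying [add_units()] and [add_leg()] to every
#' document body in a batch.
#'
#' @param docs list of \code{description_doc}.
#' @param unit unit token for [add_units()].
#' @param leg whether to apply [add_leg()].
#' @return The batch with normalized text.
#' @export
normalize_batch <- function(docs, unit = "mm", leg = TRUE) {
  lapply(docs, function(d) {
    d$text <- add_units(d$text, unit)
    if (leg) d$text <- add_leg(d$text)
    d
  })
}
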