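#' Parse one spacer-set token
#'
#' Template spacer sets use a compact syntax: comma-separated values and/or
#' `a..b` integer ranges, e.g. `"12..17"` or `"3,13,14"` or `"6..10,13"`.
#'
#' @param token Character scalar.
#' @return Sorted integer vector.
#' @keywords internal
parse_spacer_set <- function(token) {
  parts <- strsplit(trimws(token), ",", fixed = TRUE)[[1]]
  vals <- integer(0)
  for (p in parts) {
    p <- trimws(p)
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
      if (ab[1] > ab[2]) stop("empty range in spacer set: ", p)
      vals <- c(vals, ab[1]:ab[2])
    } else if (grepl("^\\d+$", p)) {
      vals <- c(vals, as.integer(p))
    } else {
      stop("cannot parse spacer set token: '", token, "'")
    }
  }
  sort(unique(vals))
}

#' Read an nsLTP type-template registry
#'
#' A registry is a TSV with columns `type_name`, `s1` .. `s5`; each spacer
#' column uses the syntax of [parse_spacer_set()]. Registry row order is
#' meaningful: it breaks ties when a motif matches several types.
#'
#' @param path Path to a registry TSV; default: the bundled templates for
#'   the eight potato types (I, II, IV, V, VII, VIII, XII, XIII).
#' @return A list of templates, each `list(type_name, allowed)` where
#'   `allowed` is a list of 5 integer vectors; class `"ltp_templates"`.
#' @export
read_templates <- function(path = ltp_extdata("ecm_templates.tsv")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("type_name", paste0("s", 1:5))
  if (!all(need %in% names(df))) {
    stop("template registry must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$type_name)) stop("duplicate type_name in registry")
  out <- lapply(seq_len(nrow(df)), function(i) {
    allowed <- lapply(paste0("s", 1:5), function(cn) {
      v <- parse_spacer_set(as.character(df[[cn]][i]))
      if (length(v) == 0) stop("empty allowed set for ", df$type_name[i])
      v
    })
    list(type_name = df$type_name[i], allowed = allowed)
  })
  names(out) <- df$type_name
  class(out) <- "ltp_templates"
  out
}

#' Bundled potato type templates (cached)
#' @return See [read_templates()].
#' @export
default_templates <- function() {
  if (is.null(.ltp_cache$templates)) {
    .ltp_cache$templates <- read_templates()
  }
  .ltp_cache$templates
}
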