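# Gene-protein-reaction (GPR) rules: boolean expressions over gene symbols
# with AND/OR and parentheses. A rule is kept both as text and as its
# disjunctive normal form, a list of enzyme "complexes" (each a character
# vector of gene symbols that must all be present).

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean GPR expression such as `"(A and B) or C"` into its
#' disjunctive normal form: a list of enzyme complexes, each a set of gene
#' symbols. `and`/`or` are case-insensitive; symbols are compared
#' case-sensitively after trimming. The empty string parses to an empty rule
#' (no complexes), used for spontaneous and exchange reactions.
#'
#' @param text GPR rule as a single string.
#' @return An object of class `"gpr"` with elements `text` (the input,
#'   trimmed) and `complexes` (list of character vectors, de-duplicated).
#' @examples
#' parse_gpr("(NDUFA11 and NDUFA9) or PYGB")
#' parse_gpr("")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text)) text <- ""
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) {
    return(structure(list(text = "", complexes = list()), class = "gpr"))
  }
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  cx <- gpr_parse_or(st)
  if (st$pos <= length(st$toks$type)) {
    stop(sprintf("GPR parse error at position %d: unexpected '%s'",
                 st$toks$at[st$pos], st$toks$val[st$pos]), call. = FALSE)
  }
  # radix sort = C-locale ordering, independent of the session locale
  cx <- unique(lapply(cx, function(s) sort(unique(s), method = "radix")))
  structure(list(text = text, complexes = cx), class = "gpr")
}

gpr_tokenize <- function(text) {
  type <- character(0); val <- character(0); at <- integer(0)
  i <- 1L; nch <- nchar(text)
  while (i <= nch) {
    ch <- substr(text, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      type <- c(type, ch); val <- c(val, ch); at <- c(at, i); i <- i + 1L
      next
    }
    m <- regmatches(substr(text, i, nch),
                    regexpr("^[^()[:space:]]+", substr(text, i, nch)))
    if (length(m) == 0L) {
      stop(sprintf("GPR parse error at position %d", i), call. = FALSE)
    }
    low <- tolower(m)
    type <- c(type, if (low %in% c("and", "or")) low else "sym")
    val <- c(val, m); at <- c(at, i)
    i <- i + nchar(m)
  }
  list(type = type, val = val, at = at)
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks$type)) NA_character_ else st$toks$type[st$pos]
}

gpr_parse_or <- function(st) {
  cx <- gpr_parse_and(st)
  while (identical(gpr_peek(st), "or")) {
    st$pos <- st$pos + 1L
    cx <- c(cx, gpr_parse_and(st))
  }
  cx
}

gpr_parse_and <- function(st) {
  cx <- gpr_parse_atom(st)
  while (identical(gpr_peek(st), "and")) {
    st$pos <- st$pos + 1L
    rhs <- gpr_parse_atom(st)
    cx <- unlist(lapply(cx, function(a) lapply(rhs, function(b) c(a, b))),
                 recursive = FALSE)
  }
  cx
}

gpr_parse_atom <- function(st) {
  tp <- gpr_peek(st)
  if (is.na(tp)) {
    stop("GPR parse error: unexpected end of expression (dangling operator?)",
         call. = FALSE)
  }
  if (tp == "sym") {
    v <- st$toks$val[st$pos]
    st$pos <- st$pos + 1L
    return(list(v))
  }
  if (tp == "(") {
    open_at <- st$toks$at[st$pos]
    st$pos <- st$pos + 1L
    cx <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) {
      stop(sprintf("GPR parse error: unbalanced parenthesis opened at position %d",
                   open_at), call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(cx)
  }
  stop(sprintf("GPR parse error at position %d: unexpected '%s'",
               st$toks$at[st$pos], st$toks$val[st$pos]), call. = FALSE)
}

#' @export
format.gpr <- function(x, ...) {
  if (length(x$complexes) == 0L) return("")
  paste(vapply(x$complexes, function(s) {
    if (length(s) > 1L) paste0("(", paste(s, collapse = " and "), ")") else s
  }, character(1)), collapse = " or ")
}

#' @export
print.gpr <- function(x, ...) {
  if (length(x$complexes) == 0L) {
    cat("<gpr: empty>\n")
  } else {
    cat("<gpr>", format(x), "\n")
  }
  invisible(x)
}

#' Genes mentioned by a GPR rule
#' @param gpr object returned by [parse_gpr()].
#' @return character vector of unique gene symbols.
#' @export
gpr_genes <- function(gpr) {
  stopifnot(inherits(gpr, "gpr"))
  sort(unique(unlist(gpr$complexes)))
}
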