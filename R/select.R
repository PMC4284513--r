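#' Select atoms by expression
#'
#' A small MDAnalysis/VMD-flavoured selection language over a [topology()].
#' Supported terms:
#' \describe{
#'   \item{`resname NAME...`}{residue-name match, e.g. `resname ARG LYS`}
#'   \item{`name NAME...`}{atom-name match, e.g. `name NE NH1 NH2`}
#'   \item{`resid N`, `resid A-B`}{residue numbers; ranges are closed,
#'     `resid 247-260` includes both ends; several tokens may be mixed}
#'   \item{`chain X...`}{subunit / chain labels}
#' }
#' Terms combine with `and` (intersection) and `or` (union); `and` binds
#' tighter than `or`; parentheses group. The result is a deterministic sorted
#' set of 1-based atom indices; an empty result warns but is not an error.
#'
#' @param topo a [topology()].
#' @param expression selection string.
#' @return sorted integer vector of atom indices (1-based).
#' @examples
#' topo <- topology(data.frame(
#'   name = c("NE", "NH1", "NH2", "NZ"),
#'   residue_number = c(249, 249, 249, 358),
#'   residue_name = c("ARG", "ARG", "ARG", "LYS"),
#'   subunit = "A"))
#' select(topo, "resname ARG and name NE NH1 NH2")
#' select(topo, "resid 247-260 and chain A")
#' @export
select <- function(topo, expression) {
  stopifnot(inherits(topo, "topology"), is.character(expression))
  toks <- strsplit(gsub("([()])", " \\1 ", expression), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("empty selection expression")
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$pos <- 1L
  res <- parse_or(env, topo)
  if (env$pos <= length(env$toks))
    stop("selection syntax error at token '", env$toks[env$pos], "'")
  if (!length(res)) warning("selection '", expression, "' matched no atoms")
  res
}

peek <- function(env) if (env$pos <= length(env$toks)) env$toks[env$pos] else NA_character_

parse_or <- function(env, topo) {
  res <- parse_and(env, topo)
  while (!is.na(peek(env)) && tolower(peek(env)) == "or") {
    env$pos <- env$pos + 1L
    res <- sort(union(res, parse_and(env, topo)))
  }
  res
}

parse_and <- function(env, topo) {
  res <- parse_primary(env, topo)
  while (!is.na(peek(env)) && tolower(peek(env)) == "and") {
    env$pos <- env$pos + 1L
    res <- sort(intersect(res, parse_primary(env, topo)))
  }
  res
}

parse_primary <- function(env, topo) {
  tok <- peek(env)
  if (is.na(tok)) stop("selection syntax error: unexpected end of expression")
  if (tok == "(") {
    env$pos <- env$pos + 1L
    res <- parse_or(env, topo)
    if (is.na(peek(env)) || peek(env) != ")")
      stop("selection syntax error: missing ')'")
    env$pos <- env$pos + 1L
    return(res)
  }
  kw <- tolower(tok)
  if (!kw %in% c("resname", "name", "resid", "chain"))
    stop("selection syntax error at token '", tok, "'")
  env$pos <- env$pos + 1L
  args <- character(0)
  repeat {
    nxt <- peek(env)
    if (is.na(nxt) || tolower(nxt) %in% c("and", "or") || nxt %in% c("(", ")"))
      break
    args <- c(args, nxt)
    env$pos <- env$pos + 1L
  }
  if (!length(args))
    stop("selection syntax error: '", tok, "' needs at least one argument")
  a <- topo$atoms
  idx <- switch(kw,
    resname = which(a$residue_name %in% args),
    name = which(a$name %in% args),
    chain = which(a$subunit %in% args),
    resid = {
      nums <- unlist(lapply(args, function(tk) {
        if (grepl("^-?[0-9]+[-:][0-9]+$", tk)) {
          m <- regmatches(tk, regexec("^(-?[0-9]+)[-:]([0-9]+)$", tk))[[1]]
          seq.int(as.integer(m[2]), as.integer(m[3]))
        } else if (grepl("^-?[0-9]+$", tk)) {
          as.integer(tk)
        } else stop("selection syntax error at token '", tk, "'")
      }))
      which(a$residue_number %in% nums)
    })
  sort(unique(idx))
}
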