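# Newick reading and writing, with optional jplace "{N}" edge annotations.

# shortest decimal representation (<= 17 significant digits) that
# round-trips to the same double
#' @keywords internal
format_brlen <- function(x) {
  vapply(x, function(v) {
    for (d in 15:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

#' Parse a Newick string
#'
#' Parses a rooted Newick tree. Branch lengths are optional but must be
#' given for all branches or for none (mixed annotation is rejected); when
#' absent they default to 0. jplace edge numbers in `{N}` tokens after
#' branch lengths are read into the tree's edge numbering. Labels are
#' restricted to `[A-Za-z0-9_.-]`; quoted or otherwise exotic labels are
#' rejected.
#'
#' @param text a single Newick string, terminated by `;`.
#' @return a [ptree()].
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tree_leaves(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text) || substr(text, nchar(text), nchar(text)) != ";") {
    stop_bp("Newick parse error: missing terminating ';'")
  }
  toks <- regmatches(text, gregexpr("[():,;]|[^():,;[:space:]]+", text))[[1]]

  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  advance <- function() {
    t <- peek(); pos <<- pos + 1L; t
  }

  parent <- integer(0); brlen <- numeric(0); label <- character(0)
  edge_num <- integer(0); order_child <- list()
  new_node <- function() {
    parent[length(parent) + 1L] <<- NA_integer_
    brlen[length(brlen) + 1L] <<- NA_real_
    label[length(label) + 1L] <<- NA_character_
    edge_num[length(edge_num) + 1L] <<- NA_integer_
    length(parent)
  }
  n_with_len <- 0L; n_without_len <- 0L

  check_label <- function(tok) {
    if (!grepl("^[A-Za-z0-9_.-]+$", tok)) {
      stop_bp("Newick parse error: invalid label token '", tok, "'")
    }
    tok
  }

  read_branch <- function(node) {
    if (peek() == ":") {
      advance()
      tok <- advance()
      m <- regmatches(tok, regexec("^([^{}]+)(\\{([0-9]+)\\})?$", tok))[[1]]
      if (length(m) == 0L) stop_bp("Newick parse error: bad branch token '", tok, "'")
      len <- suppressWarnings(as.numeric(m[2]))
      if (is.na(len)) stop_bp("Newick parse error: bad branch length '", m[2], "'")
      if (len < 0) stop_bp("Newick parse error: negative branch length '", m[2], "'")
      brlen[node] <<- len
      if (nzchar(m[4] %||% "")) edge_num[node] <<- as.integer(m[4])
      n_with_len <<- n_with_len + 1L
    } else {
      n_without_len <<- n_without_len + 1L
    }
  }

  parse_subtree <- function() {
    if (peek() == "(") {
      advance()
      node <- new_node()
      kids <- integer(0)
      repeat {
        kids <- c(kids, parse_subtree())
        t <- advance()
        if (t == ",") next
        if (t == ")") break
        stop_bp("Newick parse error: unbalanced parentheses near '", t, "'")
      }
      parent[kids] <<- node
      # optional internal label
      if (!peek() %in% c(":", ",", ")", ";", "")) label[node] <<- check_label(advance())
      read_branch(node)
      node
    } else {
      tok <- advance()
      if (tok %in% c(")", ",", ";", ":", "")) {
        stop_bp("Newick parse error: unexpected token '", tok, "'")
      }
      node <- new_node()
      label[node] <<- check_label(tok)
      read_branch(node)
      node
    }
  }

  root <- parse_subtree()
  if (advance() != ";") stop_bp("Newick parse error: trailing input before ';'")
  if (!is.na(brlen[root])) stop_bp("Newick parse error: branch length on the root is not supported")
  n_without_len <- n_without_len - 1L  # the root never has one
  if (n_with_len > 0L && n_without_len > 0L) {
    stop_bp("Newick parse error: branch lengths must be given for all branches or none")
  }
  if (n_with_len == 0L) brlen[seq_along(brlen) != root] <- 0

  # ptree() builds children lists in node-index order, which equals creation
  # order, so a parent's children keep their left-to-right string order
  ptree(parent, brlen, label, edge_num = edge_num)
}

#' Write a tree as a Newick string
#'
#' @param tr a [ptree()].
#' @param with_edge_numbers append jplace `{N}` edge-number tokens after each
#'   branch length; requires a numbered tree (see [number_edges()]).
#' @return a single Newick string ending in `;`.
#' @export
write_newick <- function(tr, with_edge_numbers = FALSE) {
  if (with_edge_numbers && anyNA(tr$edge_num[-tr$root])) {
    stop_bp("tree has unnumbered edges; call number_edges() first")
  }
  render <- function(v) {
    s <- if (is_leaf(tr, v)) {
      tr$label[v]
    } else {
      paste0("(", paste(vapply(tr$children[[v]], render, character(1)),
                        collapse = ","), ")",
             if (!is.na(tr$label[v])) tr$label[v] else "")
    }
    if (v != tr$root) {
      s <- paste0(s, ":", format_brlen(tr$brlen[v]),
                  if (with_edge_numbers) paste0("{", tr$edge_num[v], "}") else "")
    }
    s
  }
  paste0(render(tr$root), ";")
}
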