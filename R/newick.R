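#' Write a planted tree in Newick format
#'
#' The planted root is encoded as a unary root vertex; inner vertices carry
#' their ids as internal node labels.  Optional per-vertex annotations are
#' written in bracketed comment blocks after the vertex name, e.g.
#' `a[&time=0]` or `u1[&time=2,mu=E:B]` (keys `time=` for time maps and
#' `mu=` for reconciliation images; vertex images are written `V:<id>`,
#' edge images `E:<child id>`).
#'
#' @param tree a `planted_tree`
#' @param tau optional named numeric time map to embed as `time=`
#' @param mu optional reconciliation map (see [relaxed_scenario()]) to
#'   embed as `mu=`
#' @param file optional path; if `NULL` the Newick string is returned
#' @return the Newick string, invisibly when written to a file
#' @export
write_newick <- function(tree, tau = NULL, mu = NULL, file = NULL) {
  ann <- function(v) {
    parts <- character(0)
    if (!is.null(tau) && v %in% names(tau))
      parts <- c(parts, paste0("time=", format(tau[[v]], digits = 17)))
    if (!is.null(mu) && v %in% names(mu)) {
      im <- mu[[v]]
      parts <- c(parts, paste0("mu=", if (im$type == "vertex") paste0("V:", im$id)
                                      else paste0("E:", im$id)))
    }
    if (length(parts)) paste0("[&", paste(parts, collapse = ","), "]") else ""
  }
  rec <- function(v) {
    ch <- tree_children(tree, v)
    if (length(ch) == 0L) return(paste0(v, ann(v)))
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")", v, ann(v))
  }
  s <- paste0(rec(tree$root), ";")
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Read a planted tree from Newick
#'
#' Parses the dialect written by [write_newick()].  A unary root vertex is
#' interpreted as the planted root; if the root has more than one child, a
#' fresh planted root `"0"` is added above it.  Unnamed inner vertices get
#' generated ids.
#'
#' @param x a Newick string or a path to a file containing one
#' @return a list with elements `tree` (a `planted_tree`), `tau` (named
#'   numeric or `NULL`) and `mu` (named list or `NULL`)
#' @export
read_newick <- function(x) {
  if (length(x) == 1L && !grepl("[();]", x) && file.exists(x)) x <- readLines(x)
  s <- paste(x, collapse = "")
  s <- sub(";\\s*$", "", trimws(s))
  pos <- 1L; n <- nchar(s)
  counter <- new.env(); counter$i <- 0L
  peek <- function() if (pos > n) "" else substr(s, pos, pos)
  parent <- character(0); tau <- numeric(0); mu <- list()
  fresh <- function() { counter$i <- counter$i + 1L; paste0(".n", counter$i) }
  read_name <- function() {
    start <- pos
    while (pos <= n && !substr(s, pos, pos) %in% c("(", ")", ",", "[", ";")) pos <<- pos + 1L
    trimws(substr(s, start, pos - 1L))
  }
  read_annotation <- function(v) {
    if (peek() != "[") return(invisible(NULL))
    close <- regexpr("]", substr(s, pos, n), fixed = TRUE)
    if (close < 0L) stop("unterminated annotation block")
    blk <- substr(s, pos + 1L, pos + close - 2L)
    pos <<- pos + close
    blk <- sub("^&", "", blk)
    for (kv in strsplit(blk, ",", fixed = TRUE)[[1L]]) {
      key <- sub("=.*", "", kv); val <- sub("^[^=]*=", "", kv)
      if (key == "time") tau[v] <<- as.numeric(val)
      if (key == "mu") {
        typ <- sub(":.*", "", val); id <- sub("^[^:]*:", "", val)
        mu[[v]] <<- list(type = if (typ == "V") "vertex" else "edge", id = id)
      }
    }
  }
  read_clade <- function() {
    kids <- character(0)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        kids <- c(kids, read_clade())
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed Newick string near position ", pos)
      }
    }
    nm <- read_name()
    # strip branch length if present
    nm <- sub(":[-0-9.eE+]*$", "", nm)
    if (nm == "") nm <- fresh()
    for (k in kids) parent[k] <<- nm
    read_annotation(nm)
    nm
  }
  root <- read_clade()
  parent[root] <- NA_character_
  nkids <- sum(!is.na(parent) & parent == root)
  if (nkids > 1L) {
    plant <- if ("0" %in% names(parent)) fresh() else "0"
    parent[root] <- plant
    parent[plant] <- NA_character_
  }
  list(tree = planted_tree(parent),
       tau = if (length(tau)) tau else NULL,
       mu = if (length(mu)) mu else NULL)
}
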