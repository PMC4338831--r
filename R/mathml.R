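# MathML <-> R expression translation (the SBML Level 2 subset).
#
# Expressions are plain quoted R calls over species/parameter/compartment
# ids plus the symbol `time`. Supported vocabulary: arithmetic
# (+ - * / ^), exp/log/sqrt/abs/floor/ceiling, n-ary min/max, relational
# operators, and/or/not, ifelse (MathML piecewise), numeric constants and
# booleans. Function definitions are inlined by the SBML reader before
# translation, so lambdas never reach the evaluator.

MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' @importFrom xml2 xml_name xml_children xml_attr xml_text xml_add_child
NULL

mathml_unsupported <- function(what) {
  stop("unsupported MathML construct: ", what, call. = FALSE)
}

# ---- MathML -> R ----------------------------------------------------------

# node: an xml2 node whose local name is 'math' (or a math child)
mathml_to_expr <- function(node) {
  kids <- xml2::xml_children(node)
  if (xml2::xml_name(node) == "math") {
    if (length(kids) != 1L) mathml_unsupported("empty or multi-child <math>")
    return(mathml_to_expr(kids[[1L]]))
  }
  name <- xml2::xml_name(node)
  switch(name,
    ci = as.name(trimws(xml2::xml_text(node))),
    cn = mathml_parse_cn(node),
    csymbol = {
      url <- xml2::xml_attr(node, "definitionURL")
      if (!is.null(url) && grepl("time$", url)) as.name("time")
      else mathml_unsupported(paste0("csymbol ", url))
    },
    "true" = TRUE,
    "false" = FALSE,
    pi = as.name("pi"),
    exponentiale = quote(exp(1)),
    notanumber = NaN,
    infinity = Inf,
    apply = mathml_apply_to_expr(node),
    piecewise = mathml_piecewise_to_expr(node),
    mathml_unsupported(name)
  )
}

mathml_parse_cn <- function(node) {
  type <- xml2::xml_attr(node, "type")
  if (!is.na(type) && type == "e-notation") {
    parts <- xml2::xml_contents(node)
    texts <- trimws(xml2::xml_text(parts[xml2::xml_name(parts) != "sep"]))
    texts <- texts[nzchar(texts)]
    if (length(texts) != 2L) mathml_unsupported("malformed e-notation <cn>")
    return(as.numeric(texts[1L]) * 10^as.numeric(texts[2L]))
  }
  if (!is.na(type) && type == "rational") {
    parts <- xml2::xml_contents(node)
    texts <- trimws(xml2::xml_text(parts[xml2::xml_name(parts) != "sep"]))
    texts <- texts[nzchar(texts)]
    return(as.numeric(texts[1L]) / as.numeric(texts[2L]))
  }
  as.numeric(trimws(xml2::xml_text(node)))
}

mathml_apply_to_expr <- function(node) {
  kids <- xml2::xml_children(node)
  if (length(kids) == 0) mathml_unsupported("empty <apply>")
  op <- xml2::xml_name(kids[[1L]])
  args <- lapply(kids[-1L], mathml_to_expr)
  nary <- function(fun, identity_val) {
    if (length(args) == 0) return(identity_val)
    Reduce(function(a, b) call(fun, a, b), args)
  }
  switch(op,
    plus = nary("+", 0),
    times = nary("*", 1),
    minus = {
      if (length(args) == 1L) call("-", args[[1L]])
      else if (length(args) == 2L) call("-", args[[1L]], args[[2L]])
      else mathml_unsupported("minus with >2 arguments")
    },
    divide = call("/", args[[1L]], args[[2L]]),
    power = call("^", args[[1L]], args[[2L]]),
    root = {
      # default degree 2; explicit <degree> supported
      if (length(kids) >= 2L && xml2::xml_name(kids[[2L]]) == "degree") {
        deg <- mathml_to_expr(xml2::xml_child(kids[[2L]]))
        call("^", mathml_to_expr(kids[[3L]]), call("/", 1, deg))
      } else {
        call("sqrt", args[[1L]])
      }
    },
    exp = call("exp", args[[1L]]),
    ln = call("log", args[[1L]]),
    log = {
      if (length(kids) >= 2L && xml2::xml_name(kids[[2L]]) == "logbase") {
        base <- mathml_to_expr(xml2::xml_child(kids[[2L]]))
        call("log", mathml_to_expr(kids[[3L]]), base)
      } else {
        call("log", args[[1L]], 10)
      }
    },
    abs = call("abs", args[[1L]]),
    floor = call("floor", args[[1L]]),
    ceiling = call("ceiling", args[[1L]]),
    min = as.call(c(as.name("min"), args)),
    max = as.call(c(as.name("max"), args)),
    lt = call("<", args[[1L]], args[[2L]]),
    leq = call("<=", args[[1L]], args[[2L]]),
    gt = call(">", args[[1L]], args[[2L]]),
    geq = call(">=", args[[1L]], args[[2L]]),
    eq = call("==", args[[1L]], args[[2L]]),
    neq = call("!=", args[[1L]], args[[2L]]),
    and = nary("&", TRUE),
    or = nary("|", FALSE),
    not = call("!", args[[1L]]),
    ci = {
      # user-defined function application: caller must inline beforehand
      as.call(c(as.name(trimws(xml2::xml_text(kids[[1L]]))), args))
    },
    mathml_unsupported(op)
  )
}

mathml_piecewise_to_expr <- function(node) {
  kids <- xml2::xml_children(node)
  pieces <- kids[xml2::xml_name(kids) == "piece"]
  otherwise <- kids[xml2::xml_name(kids) == "otherwise"]
  expr <- if (length(otherwise) == 1L) {
    mathml_to_expr(xml2::xml_child(otherwise[[1L]]))
  } else {
    0
  }
  for (p in rev(pieces)) {
    pk <- xml2::xml_children(p)
    if (length(pk) != 2L) mathml_unsupported("piece without value/condition")
    expr <- call("ifelse", mathml_to_expr(pk[[2L]]),
                 mathml_to_expr(pk[[1L]]), expr)
  }
  expr
}

# ---- R -> MathML ----------------------------------------------------------

# Adds a <math> element (with MathML namespace) holding `expr` to `parent`.
expr_to_mathml <- function(parent, expr) {
  math <- xml2::xml_add_child(parent, "math", xmlns = MATHML_NS)
  expr_to_mathml_node(math, expr)
  invisible(math)
}

expr_to_mathml_node <- function(parent, expr) {
  if (is.numeric(expr) || is.integer(expr)) {
    return(mathml_write_cn(parent, as.numeric(expr)))
  }
  if (is.logical(expr)) {
    return(xml2::xml_add_child(parent, if (expr) "true" else "false"))
  }
  if (is.name(expr)) {
    id <- as.character(expr)
    if (id == "time") {
      cs <- xml2::xml_add_child(
        parent, "csymbol", "time", encoding = "text",
        definitionURL = "http://www.sbml.org/sbml/symbols/time")
      return(cs)
    }
    if (id == "pi") return(xml2::xml_add_child(parent, "pi"))
    return(xml2::xml_add_child(parent, "ci", id))
  }
  if (!is.call(expr)) {
    stop("cannot serialize expression component of class ",
         paste(class(expr), collapse = "/"), call. = FALSE)
  }
  fun <- as.character(expr[[1L]])
  args <- as.list(expr)[-1L]
  if (fun == "(") {
    return(expr_to_mathml_node(parent, args[[1L]]))
  }
  if (fun == "ifelse") {
    pw <- xml2::xml_add_child(parent, "piecewise")
    piece <- xml2::xml_add_child(pw, "piece")
    expr_to_mathml_node(piece, args[[2L]])
    expr_to_mathml_node(piece, args[[1L]])
    other <- xml2::xml_add_child(pw, "otherwise")
    expr_to_mathml_node(other, args[[3L]])
    return(pw)
  }
  op_map <- c("+" = "plus", "-" = "minus", "*" = "times", "/" = "divide",
              "^" = "power", "<" = "lt", "<=" = "leq", ">" = "gt",
              ">=" = "geq", "==" = "eq", "!=" = "neq",
              "&" = "and", "&&" = "and", "|" = "or", "||" = "or",
              "!" = "not", exp = "exp", abs = "abs", floor = "floor",
              ceiling = "ceiling", min = "min", max = "max", sqrt = "root")
  if (fun == "log") {
    ap <- xml2::xml_add_child(parent, "apply")
    if (length(args) == 1L) {
      xml2::xml_add_child(ap, "ln")
      expr_to_mathml_node(ap, args[[1L]])
    } else {
      xml2::xml_add_child(ap, "log")
      lb <- xml2::xml_add_child(ap, "logbase")
      expr_to_mathml_node(lb, args[[2L]])
      expr_to_mathml_node(ap, args[[1L]])
    }
    return(ap)
  }
  if (!fun %in% names(op_map)) {
    stop("cannot serialize function '", fun, "' to MathML", call. = FALSE)
  }
  ap <- xml2::xml_add_child(parent, "apply")
  xml2::xml_add_child(ap, op_map[[fun]])
  for (a in args) expr_to_mathml_node(ap, a)
  ap
}

mathml_write_cn <- function(parent, value) {
  if (is.infinite(value)) {
    return(xml2::xml_add_child(parent, "infinity"))
  }
  # plain decimal with 17 significant digits: exact double round-trip and
  # valid as a MathML real (no exponent marker)
  txt <- format(value, digits = 17, scientific = FALSE, trim = TRUE)
  xml2::xml_add_child(parent, "cn", txt)
}
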