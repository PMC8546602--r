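# Independent expression oracle: generates a random well-formed expression
# as text while computing its value directly with R arithmetic during
# generation. No parsing is involved, so agreement with
# parse_expression() + evaluate_expression() is a genuine two-route check.

random_expression <- function(depth, binding) {
  literal <- function() {
    v <- round(stats::runif(1, 0.1, 9.9), 3)
    list(text = format(v, digits = 15, scientific = FALSE), value = v)
  }
  leaf <- function() {
    if (length(binding) && stats::runif(1) < 0.6) {
      nm <- sample(names(binding), 1)
      list(text = nm, value = unname(binding[[nm]]))
    } else {
      literal()
    }
  }
  build <- function(d) {
    if (d <= 0 || stats::runif(1) < 0.2) return(leaf())
    pick <- sample(c("add", "sub", "mul", "div", "neg", "fun1", "fun2"), 1)
    a <- build(d - 1)
    if (pick == "neg") {
      return(list(text = sprintf("-(%s)", a$text), value = -a$value))
    }
    if (pick == "fun1") {
      fn <- sample(c("sin", "cos", "tan", "sqrt", "abs"), 1)
      if (fn == "sqrt") {
        # keep the argument nonnegative with an explicit abs() wrapper
        return(list(text = sprintf("sqrt(abs(%s))", a$text),
                    value = sqrt(abs(a$value))))
      }
      return(list(text = sprintf("%s(%s)", fn, a$text),
                  value = get(fn)(a$value)))
    }
    b <- build(d - 1)
    if (pick == "fun2") {
      fn <- sample(c("min", "max"), 1)
      return(list(text = sprintf("%s(%s, %s)", fn, a$text, b$text),
                  value = get(fn)(a$value, b$value)))
    }
    if (pick == "div") {
      tries <- 0
      while (abs(b$value) < 1e-3 && tries < 20) {
        b <- build(d - 1)
        tries <- tries + 1
      }
      if (abs(b$value) < 1e-3) b <- literal()
      return(list(text = sprintf("(%s) / (%s)", a$text, b$text),
                  value = a$value / b$value))
    }
    op <- c(add = "+", sub = "-", mul = "*")[[pick]]
    list(text = sprintf("(%s) %s (%s)", a$text, op, b$text),
         value = get(op)(a$value, b$value))
  }
  build(depth)
}

random_binding <- function(n_params = 3) {
  nms <- sample(c("width", "height", "arrowhead_width", "pad", "r_1"), n_params)
  stats::setNames(round(stats::runif(n_params, 0.1, 10), 3), nms)
}

# one randomized oracle-vs-implementation comparison; returns the relative
# error (cases where the oracle value is huge or non-finite are resampled)
expression_oracle_relerr <- function(depth = 4) {
  repeat {
    binding <- random_binding()
    gen <- random_expression(depth, binding)
    if (is.finite(gen$value) && abs(gen$value) < 1e9) break
  }
  got <- evaluate_expression(parse_expression(gen$text), binding)
  abs(got - gen$value) / max(1, abs(gen$value))
}
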