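# Shared fixture builders (all data is generated in code).

# minimal curated two-class dataset with named descriptors
make_tiny_dataset <- function(n = 20, p = 4, seed = 42, effect = 2) {
  set.seed(seed)
  labels <- rep(c(1L, 2L), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("C%02d", 1:n), sprintf("D%d", 1:p)))
  x[, 1] <- x[, 1] + ifelse(labels == 1L, -effect / 2, effect / 2)
  labeled_dataset(x, labels)
}

# write a labeled dataset (or raw fields) to a temp CSV, return the path
write_tiny_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# constant predictor with the package's predict() contract
constant_model <- function(class) structure(list(class = class), class = "const_model")
predict.const_model <- function(object, newdata, ...) {
  rep(object$class, nrow(as.matrix(newdata)))
}
# register so predict() dispatches inside package code during tests
.S3method("predict", "const_model", predict.const_model)
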