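# Hand-built tiny fixtures used across the unit tests. Values are chosen so
# per-sample means are computable by eye.

tiny_db <- function() {
  trait_db(data.frame(
    code = c("agrogit", "anthcot", "chenalb", "poa_ann", "silenut", "ranuacr"),
    genus = c("Agrostemma", "Anthemis", "Chenopodium", "Poa", "Silene",
              "Ranunculus"),
    epithet = c("githago", "cotula", "album", "annua", "nutans", "acris"),
    SLA     = c(20,  30,  25,  18,  22,  28),
    ARNODE  = c(40,  10,  20,  15,  30,  25),
    LOGCANH = c(1.0, 2.0, 3.0, 1.5, 2.5, 2.0),
    LOGCAND = c(0.5, 1.5, 1.0, 0.8, 1.2, 1.4),
    VEGPROP = c(0,   1,   NA,  0,   0,   1),
    LIFEHIST = c("annual", "annual", "annual", "annual", "perennial",
                 "perennial"),
    stringsAsFactors = FALSE), version = "test-1")
}

tiny_flowper <- function() {
  c(agrogit = 2, anthcot = 5, chenalb = 6, poa_ann = 8, silenut = 3,
    ranuacr = 4)
}

tiny_counts <- function() {
  m <- matrix(c(66,  0, 12,
                 0,  4,  3,
                 0,  9,  5,
                 2,  0,  0),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("agrogit", "anthcot", "chenalb", "poa_ann"),
                              c("s1", "s2", "s3")))
  m
}

# random two-group Gaussian instance on a custom predictor set
random_instance <- function(p = NULL, n_max = 60) {
  if (is.null(p)) p <- sample(1:5, 1)
  n1 <- sample((p + 2):n_max, 1)
  n2 <- sample((p + 2):n_max, 1)
  A <- matrix(rnorm(p * p, sd = 0.4), p)
  S <- crossprod(A) + diag(p)                       # SPD within-group cov
  R <- chol(S)
  mu1 <- rnorm(p); mu2 <- mu1 + rnorm(p, sd = 1.5)
  draw <- function(mu, n) sweep(matrix(rnorm(n * p), n) %*% R, 2, mu, "+")
  X <- rbind(draw(mu1, n1), draw(mu2, n2))
  colnames(X) <- paste0("X", seq_len(p))
  md <- as_model_data(
    data.frame(group = rep(c(1L, 2L), c(n1, n2)), X, check.names = FALSE),
    model = colnames(X))
  ntest <- 20
  Xt <- draw(if (runif(1) < 0.5) mu1 else mu2, ntest)
  colnames(Xt) <- colnames(X)
  list(md = md, test = as.data.frame(Xt), p = p, n1 = n1, n2 = n2)
}
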