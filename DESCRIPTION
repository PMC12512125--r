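Package: cryptMendel
Title: Privacy-Preserving Mendelian Variant Filtering with Homomorphic
    Encryption Circuits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Filters rare-disease candidate variants from multi-sample VCF
    genotypes under recessive, dominant and de novo inheritance models using
    encrypted-domain arithmetic circuits. Genotypes are encoded as two
    allele-channel bit matrices, packed into fixed-size SIMD slot blocks and
    processed by multiplication-intensive (MUL-IN) or addition-intensive
    (ADD-IN) filtering circuits that return either an encrypted match count
    or a masked, shuffled residual vector whose zeros mark matching variants.
    A bit-exact plaintext mock backend with full operation and
    multiplicative-depth instrumentation makes every circuit verifiable; key
    management supports committee-based distributed key generation and
    interactive threshold decryption. Includes a synthetic trio/cohort VCF
    generator with implanted causal variants and ground-truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
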