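# barcodeCNN

Taxonomic classification of DNA barcodes with a character-level temporal
convolutional network.

## What this package does

DNA barcoding identifies organisms from a short standardized marker
(typically a ~650 bp COI fragment). Given barcode sequences over the
alphabet `{A, C, G, T, -}` labelled with taxonomic orders — e.g. nine-order
exports from the Barcode of Life Data Systems (BOLD) — `barcodeCNN` trains
a 1D convolutional network to predict the order of an unseen sequence.

The pipeline follows the text-classification treatment of DNA:

1. **3-1 codon encoding.** Each non-overlapping trinucleotide maps to one
   of 125 dictionary symbols (the index of a k-mer is its base-5 positional
   value under `A < C < G < T < -`, so the dictionary is canonical and
   losslessly decodable). Raw single-character mode (D = 5) is the control.
2. **One-hot quantization.** A token stream becomes a binary D x L frame
   (one row per symbol, one column per position; zero-padded/truncated).
3. **Temporal CNN.** Convolution and max-pooling over sequence position,

   h(y) = sum_{x=1..k} f(x) g(yd − x + c),   h(y) = max_{x=1..k} g(yd − x + c),

   with offset constant c = k − d + 1 and output length floor((n−k)/d) + 1,
   stacked into a configurable network ending in a C-way softmax. The
   default is a motif-scanner: 128 width-5 kernels, global temporal
   max-pooling, one 64-unit hidden layer.
4. **Evaluation.** Confusion matrix; accuracy = trace/total; per-class
   recall and precision; unweighted (macro) averages.

A seeded synthetic-barcode generator (9 balanced classes, 658 ± 20 bp,
class-specific codon-aligned 9-mer motifs, substitution noise and gap
injection) stands in for the BOLD download, so everything is testable
offline. See the vignette (`vignettes/barcodeCNN-methods.Rmd`) for the
model, its assumptions, and the design decisions.

## Worked example

```r
library(barcodeCNN)

# the 3-1 encoding
d <- buildDictionary()            # 125 trinucleotide symbols
tokens(encodeSequence("ACGTAC", d))
#> [1]  7 76                      # ACG = 0*25+1*5+2,  TAC = 3*25+0*5+1
toPrintable(encodeSequence("ACGTAC", d), d)
#> [1] "*p"                       # printable serialization for CSV files

# synthetic nine-order benchmark: 1800 records, 78.72/11.45/9.83 split
bs    <- simulateBenchmark(seed = 1)
parts <- splitDataset(bs, splitSpec(seed = 1))
model <- buildModel(modelConfig(seed = 1))          # 125 x 258 frames, 9 classes
cfg   <- trainConfig(seed = 1, mode = "encoded")    # Adam, 20 epochs
fit   <- trainClassifier(model, parts$train, parts$cv, cfg)
cm    <- evaluateModel(fit$bestModel, parts$test, cfg)
classifierMetrics(cm)
#> accuracy        = 0.982955
#> macro_recall    = 0.985763
#> macro_precision = 0.980598
#> n               = 176
```

The run takes about a minute on one CPU. Accuracy is the fraction of the
176 held-out records assigned to the right order; macro recall/precision
average the per-order rates without weighting by class size. The
exact-substring motif baseline (`motifRuleClassify()`) reaches ~0.93 on
this data; the network does better because its kernels also match
partially mutated motifs. The same sequences in raw single-character mode
(`mode = "raw"`) learn far more slowly — the contrast the encoding exists
to demonstrate.

A command-line front end wraps the same functions:

```sh
Rscript inst/scripts/barcodecnn simulate --output data.csv --seed 1
Rscript inst/scripts/barcodecnn train    --input data.csv --out-dir run1 --mode encoded
Rscript inst/scripts/barcodecnn evaluate --model run1/model_best.rds --input data.csv --out-dir run1/eval
```

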