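# Example run configuration: any subset of the runConfig() fields.
seed: 1
nHaploid: 8        # common down-projection size (haploid)
muSite: 1.0e-8     # mutations / site / generation
generationTime: 1  # years
numLoci: 20000
locusLength: 300
taxaCount: 6
nSims: 50000       # hABC reference-table size
kModelChoice: 1500 # accepted draws for xi model choice
kEstimation: 100   # accepted draws for hyperparameter posteriors
pods: 50           # pseudo-observed datasets per xi value
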