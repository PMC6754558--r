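# strataXY simulator configuration template.
# Read with readSimConfigYaml(); write one from R with
# writeSimConfigYaml(simConfig(...), "config.yaml").

seed: 1                  # master RNG seed; all stages derive from it
nAutosomes: 3            # autosome count
chromLength: 20000000       # autosome length, bp
sexChromLength: 50000000  # sex chromosome length, bp

# Strata must tile [0, sexChromLength), sorted, 0-based half-open.
# kind: PAR | young | old
#   PAR   : still recombining (xyDivergence and yLoss must be 0)
#   young : non-recombining, Y intact but diverged at xyDivergence/bp
#   old   : degenerate; yLoss of Y sequence/genes deleted,
#           ySilencedFraction of surviving Y gene copies silent
strata:
  - start: 0
    end: 16666667
    kind: PAR
    xyDivergence: 0.0
    yLoss: 0.0
    ySilencedFraction: 0.0
  - start: 16666667
    end: 33333333
    kind: young
    xyDivergence: 0.005
    yLoss: 0.0
    ySilencedFraction: 0.0
  - start: 33333333
    end: 50000000
    kind: old
    xyDivergence: 0.005
    yLoss: 0.9
    ySilencedFraction: 0.5

haploidDepth: 20         # lambda: mean reads/base per haploid copy
depthDispersion: 10      # negative-binomial size of window depths
polymorphismRate: 0.001  # pi: het sites per bp per individual
nMales: 3
nFemales: 3
nGenesPerChrom: 200
rnaDepth: 40             # mean RNA reads per het site
meanHetSites: 5          # mean het sites per gene
aseTheta: 0.9            # X-allele fraction for decayed-Y genes
compensation: true       # chromosome-wide dosage compensation
kmerErrorRate: 0.0       # per-base error in emitted reads
windowSize: 50000         # analysis window, bp
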