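{
  "DG":  [[0,0],[0,1],[0,2],[1,0],[1,1],[1,2]],
  "CA3": [[3,3],[3,4],[4,3],[4,4]],
  "CA1": [[6,5],[6,6],[7,5],[7,6]]
}
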