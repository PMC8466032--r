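network unknown {
}
variable X1 {
  type discrete [ 2 ] { 0, 1 };
}
variable X2 {
  type discrete [ 2 ] { 0, 1 };
}
variable X3 {
  type discrete [ 2 ] { 0, 1 };
}
probability ( X1 ) {
  table 0.29999999999999999, 0.69999999999999996;
}
probability ( X2 | X1 ) {
  (0) 0.20000000000000001, 0.80000000000000004;
  (1) 0.59999999999999998, 0.40000000000000002;
}
probability ( X3 | X1 ) {
  (0) 0.5, 0.5;
  (1) 0.90000000000000002, 0.10000000000000001;
}
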