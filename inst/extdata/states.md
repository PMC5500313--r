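# State code reference

Stable identifiers used in every input and output file. The eight alive
states are the 2 x 2 x 2 combinations of cardiovascular disease (CVD),
cognitive impairment and ADL disability; dementia is the coexistence of
cognitive impairment and disability.

| code        | alive | CVD | cognitive impairment | disability | dementia | disability type            |
|-------------|-------|-----|----------------------|------------|----------|----------------------------|
| FREE        | yes   | no  | no                   | no         | no       | NONE                       |
| CVD         | yes   | yes | no                   | no         | no       | NONE                       |
| CIND        | yes   | no  | yes                  | no         | no       | NONE                       |
| CVD_CIND    | yes   | yes | yes                  | no         | no       | NONE                       |
| DIS_OTHER   | yes   | no  | no                   | yes        | no       | OTHER_RELATED              |
| DIS_CVD     | yes   | yes | no                   | yes        | no       | CVD_RELATED                |
| DIS_DEM     | yes   | no  | yes                  | yes        | yes      | DEMENTIA_RELATED           |
| DIS_CVD_DEM | yes   | yes | yes                  | yes        | yes      | CVD_AND_DEMENTIA_RELATED   |
| DEAD_CVD    | no    | --  | --                   | --         | --       | NONE                       |
| DEAD_NONCVD | no    | --  | --                   | --         | --       | NONE                       |

The two death states are absorbing and reachable from every alive state.
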