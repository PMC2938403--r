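age,sex,q_annual
45,F,0.00211523510745615
46,F,0.00230267634511361
47,F,0.00250670678710796
48,F,0.00272879077050703
49,F,0.00297052117406404
50,F,0.00323363056900816
51,F,0.00352000331244806
52,F,0.00383168865843575
53,F,0.00417091496682953
54,F,0.0045401050953493
55,F,0.00494189306560233
56,F,0.00537914209932533
57,F,0.00585496412657205
58,F,0.00637274087299722
59,F,0.00693614663864073
60,F,0.00754917288557788
61,F,0.00821615475630189
62,F,0.0089417996485579
63,F,0.00973121797530896
64,F,0.0105899562402884
65,F,0.0115240325598326
66,F,0.0125399747599713
67,F,0.0136448611735577
68,F,0.0148463642549692
69,F,0.0161527971188552
70,F,0.0175731630937234
45,M,0.00384255365475794
46,M,0.00418273983992323
47,M,0.00455297425688028
48,M,0.00495589827828768
49,M,0.00539438310372331
50,M,0.00587154931881806
51,M,0.0063907880371542
52,M,0.00695578373750372
53,M,0.00757053891393056
54,M,0.00823940066076234
55,M,0.00896708931826773
56,M,0.0097587293077982
57,M,0.0106198822868834
58,M,0.0115565827549534
59,M,0.012575376238564
60,M,0.0136833601807226
61,M,0.0148882276515387
62,M,0.0161983139862335
63,M,0.0176226464406862
64,M,0.0191709969331683
65,M,0.0208539379125431
66,M,0.0226829013566174
67,M,0.0246702408579276
68,M,0.0268292966961868
69,M,0.0291744637247909
70,M,0.0317212618107537
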