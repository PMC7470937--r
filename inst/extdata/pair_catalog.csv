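base,name,pattern1,pattern2,target_da
A,AA_mWW_(12)(21),1 3 7 9R,1 3 7 9R,
A,AA_fWW_(16)(21),1 3 7 9R,1 3 7 9R,
A,AA_mWW_(16)(61),1 3 7 9R,1 3 7 9R,
A,AA_fWH_(18)(27),1 3 7 9R,1 3 7 9R,
A,AA_fWH_(16)(67),1 3 7 9R,1 3 7 9R,
A,AA_fWS_(19)(63),1H 3 7H 9,1H 3 7H 9,
A,AA_mHH_(67)(76),1 3 7 9R,1 3 7 9R,
A,AA_fHH_(67)(78),1 3 7 9R,1 3 7 9R,
A,AA_mHH_(78)(87),1 3 7 9R,1 3 7 9R,
A,AA_fHS_(63)(72),1 3 7 9R,1 3 7 9R,
A,AA_mHS_(63)(79),1H 3 7 9H,1H 3 7 9H,
A,AA_mHS_(72)(83),1 3 7 9R,1 3 7 9R,
A,AA_fHS_(79)(83),1H 3 7 9H,1H 3 7 9H,
A,AA_mSS_(23)(32),1 3 7 9R,1 3 7 9R,
A,AA_mSS_(39)(93),1 3 7 9H,1 3 7 9H,
G,GG_mWW_(16)(61),1H 3 7 9R,1H 3 7 9R,
G,GG_mWH_(16)(27),1H 3 7 9R,1H 3 7 9R,
G,GG_fWH_(16)(67),1H 3 7 9R,1H 3 7H 9R,
G,GG_fWH_(26)(17)(68),1H 3 7 9R,1H 3 7 9R,
G,GG_mHH_(67)(76),1H 3 7H 9H,1H 3 7H 9H,
G,GG_mSS_(23)(32),1H 3 7 9R,1H 3 7 9R,
G,GG_mSS_(39)(93),1H 3 7 9H,1H 3 7 9H,
Hx,HxHx_mWW_(16)(61),1H 3 7 9H,1H 3 7 9H,
Hx,HxHx_fWH_(17)(26),1H 3 7 9R,1H 3 7 9R,
Hx,HxHx_fWS_(13)(62),1H 3 7 9R,1H 3 7 9R,
Hx,HxHx_fHS_(68)(79),1H 3 7 9H,1H 3 7 9H,
Hx,HxHx_mSS_(23)(32),1H 3 7 9R,1H 3 7 9R,
T,TT_mWW_(23)(32),1R 3H,1R 3H,
T,TT_fWW_(23)(34),1R 3H,1R 3H,
T,TT_mWW_(34)(43),1R 3H,1R 3H,
T,TT_fWH_(34)(45),1R 3H,1R 3H,
T,TT_fWS_(21)(32),1H 3H,1H 3H,
T,TT_mSS_(12)(21),1H 3H,1H 3H,
U,UU_mWW_(23)(32),1R 3H,1R 3H,
U,UU_fWW_(23)(34),1R 3H,1R 3H,
U,UU_mWW_(34)(43),1R 3H,1R 3H,
U,UU_fWH_(34)(45),1R 3H,1R 3H,
U,UU_mHH_(45)(54),1R 3H,1R 3H,
U,UU_mHS_(41)(52),1H 3H,1H 3H,3.05;3.9
U,UU_mSS_(12)(21),1H 3H,1H 3H,
C,CC_mWW_(23)(32),1R 3H,1R 3H,
C,CC_mWW_(24)(33)(42),1R 3,1R 3H,2.9;2.8;2.9
C,CC_mWW_(34)(43),1R 3,1R 3,
C,CC_fWH_(24)(35),1R 3,1R 3,
C,CC_mWH_(25)(34),1R 3,1R 3H,
C,CC_fWS_(26)(31)(42),1H 3,1H 3,
C,CC_mSS_(12)(21),1H 3,1H 3,
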