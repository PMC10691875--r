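samantha
sam
sarah
simon
sally
stephen
steve
susan
sophie
stella
scott
sandra
sebastian
sheila
sidney
stanley
scotland
spain
sweden
sydney
september
saturday
sunday
saturn
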